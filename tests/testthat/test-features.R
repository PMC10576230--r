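test_that("the registry defines 28 features, 17 of them baseline", {
  reg <- feature_registry()
  expect_identical(nrow(reg), 28L)
  expect_identical(sum(reg$baseline), 17L)
  expect_identical(anyDuplicated(reg$id), 0L)
  expect_setequal(unique(reg$category),
                  c("line_stability", "curve_stability", "response", "false_press"))
})

test_that("line features match hand-computed values", {
  scr <- screen_geometry(1000, 800)
  # perfect 5-sample trace over 2000 ms
  f <- line_features(perfect_trial(path_spec("line"), scr, n = 5, dt = 500), scr)
  expect_equal(unname(unlist(f)), c(0, 0, 0, 0, 0, 2000, 2, 100, 5))

  # deviations (+10, -10, +20, 0) against half-width 20 px
  sp20 <- path_spec("line", half_width_frac = 20 / 800)
  samples <- data.frame(
    x = c(200, 400, 600, 800), y = 400 + c(10, -10, 20, 0),
    t = c(0, 500, 1000, 1500), inside = TRUE
  )
  f <- line_features(mouse_trial(sp20, samples), scr)
  expect_equal(f$line_dev_mean, 5)
  expect_equal(f$line_dev_max_abs, 20)
  expect_equal(f$line_dev_net, 20)
  expect_equal(f$line_dev_total_abs, 40)
  expect_equal(f$line_dev_mean_abs, 10)
  expect_equal(f$line_pct_inside, 100)
  expect_equal(f$line_n_inside, 4)

  # same trace against half-width 15 px: the +20 sample drops out
  sp15 <- path_spec("line", half_width_frac = 15 / 800)
  f15 <- line_features(mouse_trial(sp15, samples), scr)
  expect_equal(f15$line_n_inside, 3)
  expect_equal(f15$line_pct_inside, 75)

  expect_error(line_features(perfect_trial(path_spec("sine"), scr), scr), "line")
})

test_that("curve features count membership and normalize time by width", {
  scr <- screen_geometry(1000, 800)
  f <- curve_features(perfect_trial(path_spec("sine"), scr, n = 11, dt = 500), scr)
  expect_equal(unname(unlist(f)), c(5000, 5, 100, 11))

  # spiral with every sample pushed radially outward by 2 half-widths
  sp <- path_spec("spiral")
  p <- pdtrace:::path_params(sp, scr)
  hw <- ribbon_half_width(sp, scr)
  th <- seq(pi, p$theta_max, length.out = 12)
  r <- p$b * th + 2 * hw
  tr <- mouse_trial(sp, data.frame(
    x = p$cx + r * cos(th), y = p$cy + r * sin(th),
    t = 500 * (0:11), inside = FALSE
  ))
  f <- curve_features(tr, scr)
  expect_equal(f$spiral_pct_inside, 0)
  expect_equal(f$spiral_n_inside, 0)

  expect_error(curve_features(perfect_trial(path_spec("line"), scr), scr), "sine or spiral")
})

test_that("keyboard features match arithmetic oracles", {
  # all 30 prompts resolved at exactly 400 ms, no false presses
  trials <- list(
    fixed_keyboard_trial("constant", rt = 400),
    fixed_keyboard_trial("alternating", rt = 400),
    fixed_keyboard_trial("random", rt = 400)
  )
  f <- keyboard_features(trials)
  expect_equal(f$kb_false_constant, 0)
  expect_equal(f$kb_false_total, 0)
  expect_equal(f$kb_rt_mean_constant, 400)
  expect_equal(f$kb_rt_mean_random, 400)
  expect_equal(f$kb_correct_per_rt_constant, 25)   # 10 / 0.4 s
  expect_equal(f$kb_correct_per_rt_alternating, 25)
  expect_equal(f$kb_correct_random, 10)
  expect_equal(f$kb_correct_per_rt_random, 25)

  # hand-summed false presses on the constant level
  trials[[1]] <- fixed_keyboard_trial("constant", rt = 400,
                                      n_false = c(0, 1, 0, 2, 0, 0, 1, 0, 0, 0))
  f <- keyboard_features(trials)
  expect_equal(f$kb_false_constant, 4)
  expect_equal(f$kb_false_total, 4)

  # random level: 8 of 10 resolved, resolved times averaging 500 ms
  pr <- trials[[3]]$prompts
  pr$resolved[9:10] <- FALSE
  pr$response_time[9:10] <- NA
  pr$response_time[1:8] <- c(300, 700, 500, 500, 400, 600, 450, 550)
  pr$presses[9:10] <- list(tibble::tibble(key = character(), t = integer()))
  trials[[3]] <- keyboard_trial("random", pr)
  f <- keyboard_features(trials)
  expect_equal(f$kb_correct_random, 8)
  expect_equal(f$kb_rt_mean_random, 500)
  expect_equal(f$kb_correct_per_rt_random, 16)
})

test_that("a level with no resolved prompts yields NA sentinels with a warning", {
  pr <- fixed_keyboard_trial("constant")$prompts
  pr$resolved <- FALSE
  pr$response_time <- NA
  pr$presses <- replicate(10, tibble::tibble(key = character(), t = integer()),
                          simplify = FALSE)
  trials <- list(
    keyboard_trial("constant", pr),
    fixed_keyboard_trial("alternating"),
    fixed_keyboard_trial("random")
  )
  expect_warning(f <- keyboard_features(trials), "no resolved prompts")
  expect_true(is.na(f$kb_rt_mean_constant))
  expect_true(is.na(f$kb_correct_per_rt_constant))
  expect_false(is.na(f$kb_rt_mean_alternating))
})

test_that("extract_features emits the 28 registry features deterministically", {
  s <- sim_session(17)
  fv <- extract_features(s)
  expect_identical(names(fv), feature_registry()$id)
  expect_identical(fv, extract_features(s))

  # structural inequalities hold for any session
  for (seed in c(17, 18, 19)) {
    fv <- extract_features(sim_session(seed))
    expect_lte(fv$line_dev_mean_abs, fv$line_dev_max_abs)
    expect_lte(abs(fv$line_dev_net), fv$line_dev_total_abs)
    for (sh in c("line", "sine", "spiral")) {
      n <- nrow(sim_session(seed)$mouse_trials[[sh]]$samples)
      expect_lte(fv[[paste0(sh, "_n_inside")]], n)
      expect_equal(fv[[paste0(sh, "_pct_inside")]],
                   100 * fv[[paste0(sh, "_n_inside")]] / n)
    }
  }
})

test_that("noiseless sessions score perfectly on every feature", {
  set.seed(23)
  s <- simulate_session("clean", FALSE, noiseless_params())
  fv <- extract_features(s)
  expect_lte(fv$line_dev_max_abs, 0.01)   # 2-decimal coordinate rounding
  expect_equal(fv$line_pct_inside, 100)
  expect_equal(fv$sine_pct_inside, 100)
  expect_equal(fv$spiral_pct_inside, 100)
  expect_equal(fv$kb_false_total, 0)
  expect_equal(fv$kb_correct_random, 10)
})

test_that("euclidean membership counts match the brute-force oracle on simulated trials", {
  scr <- screen_geometry(1280, 800)
  set.seed(29)
  g <- group_params(tremor_amplitude = 10, jitter_sd = 2)
  for (i in 1:10) {
    sp <- default_path_specs()[[1 + (i %% 3)]]
    tr <- simulate_mouse_trial(sp, scr, g)
    hw <- ribbon_half_width(sp, scr)
    got <- sum(is_inside_ribbon(tr$samples$x, tr$samples$y, sp, scr,
                                metric = "euclidean"))
    want <- sum(oracle_dist(tr$samples$x, tr$samples$y, sp, scr) <= hw)
    expect_identical(got, want, info = paste(sp$shape, i))
  }
})

test_that("features_to_matrix aligns rows, labels and columns", {
  cohort <- simulate_cohort(default_cohort_config(n_pd = 4, n_control = 4, seed = 3))
  m <- features_to_matrix(cohort)
  expect_identical(dim(m), c(8L, 30L))
  expect_identical(names(m)[1:2], c("session_id", "pd_status"))
  expect_identical(names(m)[-(1:2)], feature_registry()$id)
  expect_identical(m$pd_status, c(rep(1L, 4), rep(0L, 4)))
  # column values match independent per-session recomputation
  for (i in c(1, 8)) {
    expect_equal(unlist(m[i, -(1:2)]), unlist(extract_features(cohort[[i]])))
  }
  m1 <- features_to_matrix(cohort[1])
  expect_identical(dim(m1), c(1L, 30L))
  expect_error(features_to_matrix(list()), "at least one")
})

test_that("the six-feature final set maps onto registry features", {
  cohort <- simulate_cohort(default_cohort_config(n_pd = 2, n_control = 2, seed = 13))
  m <- final_model_features(features_to_matrix(cohort))
  expect_true(all(final_feature_set() %in% names(m)))
  expect_equal(m$kb_false_avg, m$kb_false_total / 3)
  expect_equal(m$kb_rt_total_constant, 10 * m$kb_rt_mean_constant)
})
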