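# small deterministic feature matrix: `signal` equals the label, the rest is noise
planted_matrix <- function(n = 60, p_noise = 9, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), n / 2)
  X <- as.data.frame(matrix(rnorm(n * p_noise), n))
  names(X) <- sprintf("noise_%02d", seq_len(p_noise))
  tibble::as_tibble(cbind(
    data.frame(session_id = sprintf("s%02d", 1:n), pd_status = y,
               signal = y + rnorm(n, 0, 0.01)),
    X
  ))
}

test_that("extra-trees importances are normalized and find a planted signal", {
  m <- planted_matrix(seed = 2)
  rk <- rank_features(m, seed = 2)
  expect_equal(sum(rk$importance), 1, tolerance = 1e-9)
  expect_identical(rk$feature[1], "signal")
  expect_identical(nrow(rk), 10L)
})

test_that("ranking is invariant to row order at a fixed seed", {
  m <- planted_matrix(seed = 3)
  rk1 <- rank_features(m, seed = 7)
  set.seed(1)
  rk2 <- rank_features(m[sample(nrow(m)), ], seed = 7)
  expect_equal(rk1, rk2)
})

test_that("ranking rejects degenerate label vectors", {
  m <- planted_matrix()
  m$pd_status <- 1L
  expect_error(rank_features(m), "both classes")
})

test_that("select_top_k preserves order and guards its bounds", {
  rk <- rank_features(planted_matrix(), seed = 1)
  expect_identical(select_top_k(rk, 10), rk$feature)
  expect_identical(select_top_k(rk, 3), rk$feature[1:3])
  expect_length(select_top_k(rk, 6), 6L)
  expect_error(select_top_k(rk, 0), "at least 1")
  expect_error(select_top_k(rk, 11), "exceeds")
})

test_that("a perfectly separating feature evaluates to F1 = 1 with SD 0", {
  m <- planted_matrix(seed = 4)
  rep <- evaluate_features(m, "signal", eval_config(n_runs = 10, seed = 4))
  g <- glance(rep)
  expect_equal(g$mean_f1, 1)
  expect_equal(g$sd_f1, 0)
  expect_equal(g$mean_balanced_accuracy, 1)
  expect_equal(g$mean_auc, 1)
})

test_that("aggregates are recomputable from the per-run values", {
  m <- planted_matrix(seed = 5)
  rep <- evaluate_features(m, c("signal", "noise_01"),
                           eval_config(n_runs = 8, seed = 5))
  runs <- tidy(rep)
  expect_identical(nrow(runs), 8L)
  g <- glance(rep)
  expect_equal(g$mean_f1, mean(runs$f1, na.rm = TRUE))
  expect_equal(g$sd_auc, sd(runs$auc, na.rm = TRUE))
  expect_true(all(runs$f1 >= 0 & runs$f1 <= 1, na.rm = TRUE))
  expect_true(all(runs$balanced_accuracy >= 0 & runs$balanced_accuracy <= 1))
})

test_that("evaluation is bit-reproducible at a fixed seed", {
  m <- planted_matrix(seed = 6)
  cfg <- eval_config(n_runs = 5, seed = 11)
  r1 <- evaluate_features(m, feature_subset = NULL, config = cfg)
  r2 <- evaluate_features(m, feature_subset = NULL, config = cfg)
  expect_equal(r1$runs, r2$runs)
  # and the full protocol too
  p1 <- screening_protocol(m, config = cfg)
  p2 <- screening_protocol(m, config = cfg)
  expect_equal(p1$ranking, p2$ranking)
  expect_equal(p1$report$runs, p2$report$runs)
})

test_that("every model family runs and returns usable scores", {
  m <- planted_matrix(n = 40, seed = 7)
  for (fam in c("random_forest", "decision_tree_regression",
                "support_vector", "multilayer_perceptron")) {
    g <- glance(evaluate_features(
      m, c("signal", "noise_01", "noise_02"),
      eval_config(n_runs = 3, seed = 7, model_family = fam)
    ))
    expect_true(is.finite(g$mean_f1), info = fam)
    # the planted signal is trivial; every family should beat chance
    expect_gt(g$mean_balanced_accuracy, 0.6)
  }
})

test_that("a constant classifier scores balanced accuracy exactly 0.5", {
  y <- factor(c(rep("pd", 7), rep("control", 13)), levels = c("control", "pd"))
  m <- pdtrace:::compute_metrics(y, rep(1, 20))
  expect_equal(m[["balanced_accuracy"]], 0.5)
  m <- pdtrace:::compute_metrics(y, rep(0, 20))
  expect_equal(m[["balanced_accuracy"]], 0.5)
})

test_that("single-class test splits warn and record NA AUC, never crash", {
  m <- planted_matrix(n = 10, seed = 8)
  m$pd_status <- c(1L, rep(0L, 9))
  m$signal <- m$pd_status + rnorm(10, 0, 0.01)
  cfg <- eval_config(n_runs = 12, seed = 8, stratified = FALSE, test_fraction = 0.2)
  w <- capture_warnings(rep <- evaluate_features(m, "signal", cfg))
  expect_true(any(grepl("single class", w)))
  expect_identical(nrow(tidy(rep)), 12L)
  expect_true(anyNA(tidy(rep)$auc))
})

test_that("the single-feature sweep covers the registry in order", {
  cohort <- simulate_cohort(default_cohort_config(n_pd = 6, n_control = 6, seed = 10))
  m <- features_to_matrix(cohort)
  sw <- single_feature_sweep(m, eval_config(n_runs = 2, seed = 10, num_trees = 100))
  expect_identical(nrow(sw), 28L)
  expect_identical(sw$feature, feature_registry()$id)
  expect_true(all(c("mean_auc", "sd_auc", "mean_balanced_accuracy", "mean_f1")
                  %in% names(sw)))
})

test_that("a pure-noise feature hovers at chance on a null cohort", {
  set.seed(12)
  m <- tibble::tibble(
    session_id = sprintf("s%02d", 1:60),
    pd_status = rep(c(1L, 0L), 30),
    noise = rnorm(60)
  )
  g <- glance(evaluate_features(m, "noise", eval_config(n_runs = 20, seed = 12)))
  expect_gt(g$mean_balanced_accuracy, 0.3)
  expect_lt(g$mean_balanced_accuracy, 0.7)
})

test_that("NA feature values are imputed from train-set medians only", {
  m <- planted_matrix(n = 30, seed = 13)
  m$signal[c(3, 17)] <- NA
  rep <- evaluate_features(m, c("signal", "noise_01"),
                           eval_config(n_runs = 4, seed = 13))
  expect_identical(nrow(tidy(rep)), 4L)
  expect_true(all(is.finite(tidy(rep)$f1)))
  m$noise_01 <- NA_real_
  expect_error(
    evaluate_features(m, c("signal", "noise_01"), eval_config(n_runs = 2, seed = 13)),
    "entirely missing"
  )
})
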