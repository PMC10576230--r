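# Shared fixtures, built in code at test time.

# Group parameters with every noise source switched off: perfect tracing,
# instant-resolution-free tapping (all prompts resolved, no false presses).
noiseless_params <- function() {
  group_params(
    tremor_amplitude = 0, jitter_sd = 0, trace_speed = 0.1, speed_cv = 0,
    rt_log_mean = log(400), rt_log_sd = 0.2,
    false_press_rate = 0, timeout_prob = 0
  )
}

# A mouse trial tracing the centerline exactly, sampled uniformly in
# arclength at `dt` ms steps.
perfect_trial <- function(spec, screen, n = 11, dt = 500) {
  cl <- instantiate_path(spec, screen, n = 2048)
  frac <- seq(0, 1, length.out = n)
  x <- stats::approx(cl$arclength_frac, cl$x, xout = frac, ties = "ordered")$y
  y <- stats::approx(cl$arclength_frac, cl$y, xout = frac, ties = "ordered")$y
  mouse_trial(spec, data.frame(x = x, y = y, t = dt * (seq_len(n) - 1), inside = TRUE))
}

# A keyboard trial where every prompt resolves at exactly `rt` ms with the
# given per-prompt false-press counts.
fixed_keyboard_trial <- function(level, rt = 400, n_false = rep(0, 10),
                                 keys = NULL) {
  prompted <- switch(level,
    constant = rep("f", 10),
    alternating = rep(c("f", "j"), 5),
    random = keys %||% letters[1:10]
  )
  presses <- lapply(seq_len(10), function(i) {
    fp <- if (n_false[i] > 0) {
      data.frame(key = rep("z", n_false[i]),
                 t = round(seq(50, rt - 50, length.out = n_false[i])))
    } else {
      data.frame(key = character(), t = integer())
    }
    rbind(fp, data.frame(key = prompted[i], t = rt))
  })
  keyboard_trial(level, data.frame(
    prompted_key = prompted, resolved = TRUE, response_time = rt,
    presses = I(presses)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracle: minimum Euclidean distance from a point to
# a very densely sampled centerline (vertex distances only).
oracle_dist <- function(x, y, spec, screen, n = 50001) {
  cl <- instantiate_path(spec, screen, n = n)
  vapply(seq_along(x), function(i) {
    sqrt(min((cl$x - x[i])^2 + (cl$y - y[i])^2))
  }, numeric(1))
}

# A small simulated session cached per seed for reuse across tests.
sim_session <- local({
  cache <- new.env()
  function(seed = 42, pd = TRUE, g = NULL) {
    key <- paste0(seed, pd, is.null(g))
    if (is.null(cache[[key]])) {
      set.seed(seed)
      cfg <- default_cohort_config(seed = seed)
      cache[[key]] <- simulate_session(
        sprintf("fixture-%d", seed), pd,
        g %||% (if (pd) cfg$pd else cfg$control),
        screen = cfg$screen
      )
    }
    cache[[key]]
  }
})

# Build a session with given demographics on top of shared motor trials
# (cheap: trials simulated once).
demo_session <- local({
  template <- NULL
  function(id, pd_status, age = NA, gender = "unspecified", race = "unspecified") {
    if (is.null(template)) {
      set.seed(99)
      template <<- simulate_session("template", FALSE, noiseless_params())
    }
    session(
      session_id = id,
      demographics = demographics(pd_status = pd_status, age = age,
                                  gender = gender, race = race),
      screen = template$screen,
      mouse_trials = unname(template$mouse_trials),
      keyboard_trials = unname(template$keyboard_trials)
    )
  }
})

# Cohort with given per-bracket age counts (overall), labels alternating.
bracket_cohort <- function(counts,
                           brackets = c("40-49", "50-59", "60-69", "70-79", "80-90"),
                           pd_counts = NULL) {
  ages <- integer(0)
  pd <- logical(0)
  for (i in seq_along(counts)) {
    lim <- as.integer(strsplit(brackets[i], "-")[[1]])
    n <- counts[i]
    if (n == 0) next
    ages <- c(ages, rep(lim[1] + 2L, n))
    k <- if (is.null(pd_counts)) 0L else pd_counts[i]
    pd <- c(pd, rep(c(TRUE, FALSE), c(k, n - k)))
  }
  lapply(seq_along(ages), function(i) {
    demo_session(sprintf("d-%02d", i), pd[i], age = ages[i])
  })
}
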