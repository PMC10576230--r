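#' Group-level generative parameters
#'
#' Parameters of the generative model for one group (PD-like or
#' control-like). Tracing: a trial's duration is
#' `(1 / trace_speed) * exp(Normal(0, speed_cv))` seconds, and at each sample
#' the cursor sits on the centerline at the elapsed arclength fraction,
#' displaced along the local path normal by an oscillatory tremor term
#' `tremor_amplitude * sin(2*pi*tremor_freq*t + phase)` plus white jitter
#' `Normal(0, jitter_sd)`. Tapping: response times are lognormal (truncated
#' at the prompt timeout), prompts go unresolved with probability
#' `timeout_prob`, and false presses per prompt are Poisson.
#'
#' @param tremor_amplitude Tremor amplitude in pixels (>= 0).
#' @param tremor_freq Tremor frequency in Hz.
#' @param jitter_sd White positional noise SD in pixels (>= 0).
#' @param trace_speed Tracing speed as fraction of path length per second (> 0).
#' @param speed_cv Log-scale SD of the per-trial speed multiplier (>= 0).
#' @param rt_log_mean,rt_log_sd Lognormal response-time parameters (log-ms).
#' @param false_press_rate Expected false presses per prompt (>= 0).
#' @param timeout_prob Probability a prompt goes unresolved (in \[0, 1\]).
#' @return A `pd_group_params` object.
#' @export
group_params <- function(tremor_amplitude = 2, tremor_freq = 5, jitter_sd = 1,
                         trace_speed = 0.08, speed_cv = 0.2,
                         rt_log_mean = log(450), rt_log_sd = 0.25,
                         false_press_rate = 0.05, timeout_prob = 0.01) {
  chk <- function(v, nm, lo = 0, hi = Inf, strict_lo = FALSE) {
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v) || v < lo || v > hi ||
        (strict_lo && v <= lo)) {
      rlang::abort(sprintf("`%s` out of range", nm))
    }
  }
  chk(tremor_amplitude, "tremor_amplitude")
  chk(tremor_freq, "tremor_freq", strict_lo = TRUE)
  chk(jitter_sd, "jitter_sd")
  chk(trace_speed, "trace_speed", strict_lo = TRUE)
  chk(speed_cv, "speed_cv")
  chk(rt_log_sd, "rt_log_sd")
  chk(false_press_rate, "false_press_rate")
  chk(timeout_prob, "timeout_prob", hi = 1)
  structure(
    list(
      tremor_amplitude = tremor_amplitude, tremor_freq = tremor_freq,
      jitter_sd = jitter_sd, trace_speed = trace_speed, speed_cv = speed_cv,
      rt_log_mean = rt_log_mean, rt_log_sd = rt_log_sd,
      false_press_rate = false_press_rate, timeout_prob = timeout_prob
    ),
    class = "pd_group_params"
  )
}

#' Cohort generation configuration
#'
#' @param n_pd,n_control Number of PD-like and control-like sessions
#'   (`n_pd + n_control >= 2`).
#' @param pd,control [group_params()] for each group.
#' @param screen The [screen_geometry()] every session reports.
#' @param sampling_interval Mouse sampling interval in ms.
#' @param seed Integer seed governing the whole cohort.
#' @param timeout_ms Keyboard prompt window in ms.
#' @param demographics Optional demographic marginals (as in the shipped
#'   default config); `NULL` leaves all demographics unspecified.
#' @return A `pd_cohort_config` object.
#' @export
cohort_config <- function(n_pd, n_control, pd = group_params(),
                          control = group_params(),
                          screen = screen_geometry(1280, 800),
                          sampling_interval = 500, seed = 1,
                          timeout_ms = 5000, demographics = NULL) {
  if (n_pd < 0 || n_control < 0 || n_pd + n_control < 2) {
    rlang::abort("need n_pd >= 0, n_control >= 0 and n_pd + n_control >= 2")
  }
  stopifnot(inherits(pd, "pd_group_params"), inherits(control, "pd_group_params"))
  structure(
    list(
      n_pd = as.integer(n_pd), n_control = as.integer(n_control),
      pd = pd, control = control, screen = screen,
      sampling_interval = as.integer(sampling_interval),
      seed = as.integer(seed), timeout_ms = as.integer(timeout_ms),
      demographics = demographics
    ),
    class = "pd_cohort_config"
  )
}

#' Default cohort configuration from the shipped parameter file
#'
#' Loads the package's default generative parameters (PD-like vs
#' control-like groups with a speed/precision trade-off, lognormal reaction
#' times and Poisson false presses) from `extdata/default_cohort.yaml`.
#'
#' @param n_pd,n_control Group sizes (defaults mirror a 13/18 cohort).
#' @param seed Integer seed.
#' @return A `pd_cohort_config`.
#' @export
#' @examples
#' cfg <- default_cohort_config(n_pd = 5, n_control = 5, seed = 1)
default_cohort_config <- function(n_pd = 13, n_control = 18, seed = 1) {
  path <- system.file("extdata", "default_cohort.yaml", package = "pdtrace")
  raw <- yaml::read_yaml(path)
  gp <- function(g) {
    group_params(
      tremor_amplitude = g$tremor_amplitude, tremor_freq = g$tremor_freq,
      jitter_sd = g$jitter_sd, trace_speed = g$trace_speed,
      speed_cv = g$speed_cv, rt_log_mean = g$rt_log_mean,
      rt_log_sd = g$rt_log_sd, false_press_rate = g$false_press_rate,
      timeout_prob = g$timeout_prob
    )
  }
  cohort_config(
    n_pd = n_pd, n_control = n_control,
    pd = gp(raw$pd), control = gp(raw$control),
    screen = screen_geometry(raw$screen$width, raw$screen$height),
    sampling_interval = raw$sampling_interval, seed = seed,
    timeout_ms = raw$keyboard$timeout_ms,
    demographics = raw$demographics
  )
}

#' Simulate one mouse tracing trial
#'
#' Draws a trial duration, then walks the centerline at constant arclength
#' speed, displacing each sample along the local path normal by the tremor
#' oscillation plus white jitter. Sampling stops at the first sample that
#' reaches the end of the path; inside flags are computed from geometry.
#' Uses the current RNG state.
#'
#' @param spec The [path_spec()] to trace.
#' @param screen A [screen_geometry()].
#' @param g [group_params()] of the participant's group.
#' @param interval Sampling interval in ms.
#' @return A [mouse_trial()].
#' @export
simulate_mouse_trial <- function(spec, screen, g, interval = 500) {
  check_spec_screen(spec, screen)
  stopifnot(inherits(g, "pd_group_params"))
  duration_ms <- 1000 * (1 / g$trace_speed) * exp(stats::rnorm(1, 0, g$speed_cv))
  phase <- stats::runif(1, 0, 2 * pi)
  t <- seq(0, by = interval, length.out = ceiling(duration_ms / interval) + 1L)
  frac <- pmin(t / duration_ms, 1)
  t <- t[seq_len(which(frac >= 1)[1])]
  frac <- frac[seq_along(t)]

  cl <- instantiate_path(spec, screen, n = 1024)
  base_x <- stats::approx(cl$arclength_frac, cl$x, xout = frac, ties = "ordered")$y
  base_y <- stats::approx(cl$arclength_frac, cl$y, xout = frac, ties = "ordered")$y
  # unit normal of the local segment at each sample's arclength position
  seg <- pmin(findInterval(frac, cl$arclength_frac, rightmost.closed = TRUE),
              nrow(cl) - 1L)
  tx <- cl$x[seg + 1L] - cl$x[seg]
  ty <- cl$y[seg + 1L] - cl$y[seg]
  norm <- sqrt(tx^2 + ty^2)
  nx <- -ty / norm
  ny <- tx / norm

  disp <- g$tremor_amplitude * sin(2 * pi * g$tremor_freq * t / 1000 + phase) +
    stats::rnorm(length(t), 0, g$jitter_sd)
  x <- round(base_x + disp * nx, 2)
  y <- round(base_y + disp * ny, 2)
  inside <- is_inside_ribbon(x, y, spec, screen)
  mouse_trial(spec, tibble::tibble(x = x, y = y, t = t, inside = inside))
}

#' Simulate one keyboard tapping trial
#'
#' Ten prompts following the level's key rule (constant key, two alternating
#' keys, or a fresh uniform random letter per prompt). Each prompt resolves
#' with probability `1 - timeout_prob`; resolved response times are
#' lognormal truncated at the timeout, and false presses per prompt are
#' Poisson, each with a key different from the prompted one and a uniform
#' time inside the window. Uses the current RNG state.
#'
#' @param level `"constant"`, `"alternating"` or `"random"`.
#' @param g [group_params()].
#' @param timeout_ms Prompt window in ms.
#' @param constant_key,alternating_keys,alphabet Key material for the three
#'   levels (the random level draws from `alphabet`).
#' @return A [keyboard_trial()].
#' @export
simulate_keyboard_trial <- function(level = c("constant", "alternating", "random"),
                                    g, timeout_ms = 5000,
                                    constant_key = "f",
                                    alternating_keys = c("f", "j"),
                                    alphabet = letters) {
  level <- rlang::arg_match(level)
  stopifnot(inherits(g, "pd_group_params"))
  n <- 10L
  prompted <- switch(level,
    constant = rep(constant_key, n),
    alternating = rep_len(alternating_keys, n),
    random = sample(alphabet, n, replace = TRUE)
  )
  resolved <- stats::runif(n) >= g$timeout_prob
  # inverse-CDF truncation of the lognormal at the timeout
  p_max <- stats::plnorm(timeout_ms, g$rt_log_mean, g$rt_log_sd)
  rt <- ifelse(
    resolved,
    pmax(1, round(stats::qlnorm(stats::runif(n) * p_max, g$rt_log_mean, g$rt_log_sd))),
    NA_real_
  )
  n_false <- stats::rpois(n, g$false_press_rate)
  presses <- lapply(seq_len(n), function(i) {
    window <- if (resolved[i]) rt[i] else timeout_ms
    key <- character(0)
    t_press <- numeric(0)
    if (n_false[i] > 0) {
      key <- sample(setdiff(alphabet, prompted[i]), n_false[i], replace = TRUE)
      t_press <- round(stats::runif(n_false[i], 0, window))
    }
    if (resolved[i]) {
      key <- c(key, prompted[i])
      t_press <- c(t_press, rt[i])
    }
    ord <- order(t_press)
    tibble::new_tibble(list(key = key[ord], t = as.integer(t_press[ord])),
                       nrow = length(ord))
  })
  keyboard_trial(
    level = level,
    prompts = tibble::tibble(
      prompted_key = prompted, resolved = resolved,
      response_time = rt, presses = presses
    ),
    timeout_ms = timeout_ms
  )
}

# Sample demographics for one participant from the configured marginals.
simulate_demographics <- function(pd_status, marginals) {
  if (is.null(marginals)) return(demographics(pd_status = pd_status))
  grp <- if (pd_status) marginals$pd else marginals$control
  brackets <- marginals$age_brackets
  w <- as.numeric(grp$age_weights)
  if (sum(w) <= 0) w <- rep(1, length(brackets))
  b <- brackets[sample.int(length(brackets), 1, prob = w)]
  lim <- as.integer(strsplit(b, "-")[[1]])
  age <- sample(seq(lim[1], lim[2]), 1)
  gw <- unlist(grp$gender_weights)
  gender <- names(gw)[sample.int(length(gw), 1, prob = pmax(as.numeric(gw), 1e-9))]
  rw <- unlist(grp$race_weights)
  race <- names(rw)[sample.int(length(rw), 1, prob = pmax(as.numeric(rw), 1e-9))]
  demographics(pd_status = pd_status, age = age, gender = gender, race = race)
}

#' Simulate one full session
#'
#' Three mouse trials (line, sine, spiral) and three keyboard trials
#' (constant, alternating, random) drawn from one group's parameters. Uses
#' the current RNG state.
#'
#' @param session_id Identifier string.
#' @param pd_status Logical group label.
#' @param g [group_params()].
#' @param screen A [screen_geometry()].
#' @param interval Mouse sampling interval in ms.
#' @param timeout_ms Keyboard prompt window in ms.
#' @param demographic_marginals Optional marginals (see shipped config).
#' @return A validated `pd_session`.
#' @export
simulate_session <- function(session_id, pd_status, g,
                             screen = screen_geometry(1280, 800),
                             interval = 500, timeout_ms = 5000,
                             demographic_marginals = NULL) {
  specs <- default_path_specs()
  mts <- lapply(specs, function(sp) simulate_mouse_trial(sp, screen, g, interval))
  kts <- lapply(c("constant", "alternating", "random"), function(lv) {
    simulate_keyboard_trial(lv, g, timeout_ms = timeout_ms)
  })
  dem <- simulate_demographics(pd_status, demographic_marginals)
  validate_session(session(session_id, dem, screen, unname(mts), kts))
}

#' Simulate a cohort of sessions
#'
#' Generates `n_pd` PD-like and `n_control` control-like sessions. The
#' cohort seed only allocates one derived substream seed per session, so a
#' session's content depends on its index and the cohort seed but not on how
#' many sessions precede it — cohorts are reproducible and composable.
#'
#' @param cfg A [cohort_config()] (see [default_cohort_config()]).
#' @return A `pd_cohort`: list of sessions, PD-like first.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(n_pd = 2, n_control = 2, seed = 7))
#' length(cohort)
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "pd_cohort_config"))
  n <- cfg$n_pd + cfg$n_control
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  is_pd <- c(rep(TRUE, cfg$n_pd), rep(FALSE, cfg$n_control))
  ids <- sprintf("%s-%03d", ifelse(is_pd, "pd", "ctl"),
                 c(seq_len(cfg$n_pd), seq_len(cfg$n_control)))
  sessions <- lapply(seq_len(n), function(i) {
    set.seed(sub_seeds[i])
    simulate_session(
      session_id = ids[i], pd_status = is_pd[i],
      g = if (is_pd[i]) cfg$pd else cfg$control,
      screen = cfg$screen, interval = cfg$sampling_interval,
      timeout_ms = cfg$timeout_ms,
      demographic_marginals = cfg$demographics
    )
  })
  structure(sessions, class = "pd_cohort")
}

#' @export
print.pd_cohort <- function(x, ...) {
  labs <- vapply(x, function(s) s$demographics$pd_status, logical(1))
  cat(sprintf("<pd_cohort> %d sessions (%d PD, %d control)\n",
              length(x), sum(labs), sum(!labs)))
  invisible(x)
}
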