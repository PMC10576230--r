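#' The feature registry
#'
#' The canonical ordered list of the 28 motor-behavior features extracted
#' from one session: 17 baseline measurements in 4 categories (straight-line
#' stability, curved-shape stability, response speed/accuracy, false
#' presses) plus 11 features derived from them (width-normalized times,
#' correct counts per unit response time, deviation aggregates, the grand
#' false-press total).
#'
#' Conventions recorded here because the feature names alone underdetermine
#' them: the "maximum vertical deviation" is the maximum of absolute
#' deviations (it dominates both tails); "with respect to window width"
#' divides by screen width in pixels; "with respect to the average time
#' taken" divides the correct-press count by the mean response time in
#' seconds.
#'
#' @return A tibble with columns `id`, `label`, `category` (one of
#'   `line_stability`, `curve_stability`, `response`, `false_press`) and
#'   `baseline` (logical; 17 `TRUE`, 11 `FALSE`).
#' @export
#' @examples
#' feature_registry()
feature_registry <- function() {
  reg <- tibble::tribble(
    ~id, ~label, ~category, ~baseline,
    "line_dev_mean", "Mean vertical deviation of tracing a straight line", "line_stability", TRUE,
    "line_dev_max_abs", "Maximum vertical deviation of tracing a straight line", "line_stability", FALSE,
    "line_dev_net", "Net vertical deviation of tracing a straight line", "line_stability", FALSE,
    "line_dev_total_abs", "Total of the absolute values of vertical deviations of tracing a straight line", "line_stability", FALSE,
    "line_dev_mean_abs", "Mean of the absolute values of vertical deviations of tracing a straight line", "line_stability", FALSE,
    "line_time", "Amount of time taken for tracing straight line", "line_stability", TRUE,
    "line_time_per_width", "Amount of time taken for tracing straight line with respect to window width", "line_stability", FALSE,
    "line_pct_inside", "Percentage of points traced in indicated width of a straight line", "line_stability", TRUE,
    "line_n_inside", "Number of points traced inside the expected width of a straight line", "line_stability", TRUE,
    "sine_time", "Time taken to trace sine wave", "curve_stability", TRUE,
    "sine_time_per_width", "Time taken to trace sine wave with respect to device window width", "curve_stability", FALSE,
    "sine_pct_inside", "Percentage of traced points inside indicated sine curve", "curve_stability", TRUE,
    "sine_n_inside", "Number of points traced inside indicated sine curve", "curve_stability", TRUE,
    "spiral_time", "Time taken to trace a spiral", "curve_stability", TRUE,
    "spiral_time_per_width", "Time taken to trace spiral with respect to device window width", "curve_stability", FALSE,
    "spiral_pct_inside", "Percentage of points traced inside the width of the indicated spiral", "curve_stability", TRUE,
    "spiral_n_inside", "Number of points traced inside the width of the indicated spiral", "curve_stability", TRUE,
    "kb_false_constant", "Total false key presses with single prompted key", "false_press", TRUE,
    "kb_false_alternating", "Total false key presses with prompt key randomly chosen from 2 options", "false_press", TRUE,
    "kb_false_random", "Total false key presses with prompt randomly chosen", "false_press", TRUE,
    "kb_false_total", "Total false key presses from all trials", "false_press", FALSE,
    "kb_rt_mean_constant", "Average response time when same key prompted", "response", TRUE,
    "kb_rt_mean_alternating", "Average response time when semirandom key prompted", "response", TRUE,
    "kb_rt_mean_random", "Average response time when random key prompted", "response", TRUE,
    "kb_correct_per_rt_constant", "Number of correctly pressed keys (when prompted with same key) with respect to the average time taken", "response", FALSE,
    "kb_correct_per_rt_alternating", "Number of correctly pressed keys (with semirandom prompt) with respect to the average time taken", "response", FALSE,
    "kb_correct_random", "Number of correctly pressed keys when prompted with a random key", "response", TRUE,
    "kb_correct_per_rt_random", "Number of correctly pressed keys (when prompted with a random key) with respect to the average time taken", "response", FALSE
  )
  stopifnot(nrow(reg) == 28L, sum(reg$baseline) == 17L)
  reg
}

#' Straight-line stability features
#'
#' The nine straight-line features: signed-deviation aggregates (mean,
#' absolute maximum, net sum, total absolute, mean absolute), trace time,
#' width-normalized trace time, and ribbon-membership percentage and count.
#'
#' @param trial A line [mouse_trial()].
#' @param screen The session's [screen_geometry()].
#' @param metric Membership convention for [is_inside_ribbon()].
#' @return A 1-row tibble with 9 columns.
#' @export
line_features <- function(trial, screen, metric = "band") {
  if (!inherits(trial, "pd_mouse_trial")) rlang::abort("`trial` must be a mouse_trial")
  if (trial$spec$shape != "line") {
    rlang::abort("line_features() needs a line trial; use curve_features() for sine/spiral")
  }
  if (nrow(trial$samples) < 2L) rlang::abort("need at least 2 samples")
  d <- vertical_deviation(trial$samples$x, trial$samples$y, trial$spec, screen)
  inside <- is_inside_ribbon(trial$samples$x, trial$samples$y, trial$spec, screen,
                             metric = metric)
  time <- trial$samples$t[nrow(trial$samples)] - trial$samples$t[1]
  n <- length(d)
  tibble::tibble(
    line_dev_mean = mean(d),
    line_dev_max_abs = max(abs(d)),
    line_dev_net = sum(d),
    line_dev_total_abs = sum(abs(d)),
    line_dev_mean_abs = mean(abs(d)),
    line_time = as.numeric(time),
    line_time_per_width = time / screen$width,
    line_pct_inside = 100 * sum(inside) / n,
    line_n_inside = as.numeric(sum(inside))
  )
}

#' Curved-shape stability features
#'
#' The four features recorded for each curved stimulus (sine or spiral):
#' trace time, width-normalized trace time, and ribbon-membership percentage
#' and count.
#'
#' @param trial A sine or spiral [mouse_trial()].
#' @inheritParams line_features
#' @return A 1-row tibble with 4 columns, prefixed by the shape name.
#' @export
curve_features <- function(trial, screen, metric = "band") {
  if (!inherits(trial, "pd_mouse_trial")) rlang::abort("`trial` must be a mouse_trial")
  shape <- trial$spec$shape
  if (shape == "line") {
    rlang::abort("curve_features() needs a sine or spiral trial; use line_features() for the line")
  }
  inside <- is_inside_ribbon(trial$samples$x, trial$samples$y, trial$spec, screen,
                             metric = metric)
  time <- trial$samples$t[nrow(trial$samples)] - trial$samples$t[1]
  n <- nrow(trial$samples)
  out <- tibble::tibble(
    time = as.numeric(time),
    time_per_width = time / screen$width,
    pct_inside = 100 * sum(inside) / n,
    n_inside = as.numeric(sum(inside))
  )
  names(out) <- paste0(shape, "_", names(out))
  out
}

#' Keyboard tapping features
#'
#' The eleven tapping features: per-level false-press totals and their grand
#' total; per-level mean response time over resolved prompts; the correct
#' count per unit mean response time (seconds) for the constant and
#' alternating levels; the raw correct count for the random level and its
#' per-unit-time analogue.
#'
#' A level with zero resolved prompts has no defined mean response time; the
#' affected features are set to `NA` with a warning and are treated as
#' missing downstream (median-imputed at modeling time).
#'
#' @param trials List of 3 [keyboard_trial()] objects in canonical order
#'   (constant, alternating, random).
#' @return A 1-row tibble with 11 columns.
#' @export
keyboard_features <- function(trials) {
  if (length(trials) != 3L ||
      !all(vapply(trials, inherits, logical(1), "pd_keyboard_trial"))) {
    rlang::abort("`trials` must be a list of exactly 3 keyboard trials")
  }
  levels <- vapply(trials, function(tr) tr$level, character(1))
  if (!identical(levels, c("constant", "alternating", "random"))) {
    rlang::abort("keyboard trials must be in canonical order: constant, alternating, random")
  }
  fp <- vapply(trials, function(tr) sum(false_presses(tr)), numeric(1))
  rt_mean <- vapply(trials, function(tr) {
    rts <- tr$prompts$response_time[tr$prompts$resolved]
    if (length(rts) == 0) {
      rlang::warn(sprintf(
        "keyboard level '%s' has no resolved prompts; its response-time features are NA",
        tr$level
      ))
      NA_real_
    } else {
      mean(rts)
    }
  }, numeric(1))
  n_correct <- vapply(trials, function(tr) sum(tr$prompts$resolved), numeric(1))
  correct_per_rt <- n_correct / (rt_mean / 1000)
  tibble::tibble(
    kb_false_constant = fp[1],
    kb_false_alternating = fp[2],
    kb_false_random = fp[3],
    kb_false_total = sum(fp),
    kb_rt_mean_constant = rt_mean[1],
    kb_rt_mean_alternating = rt_mean[2],
    kb_rt_mean_random = rt_mean[3],
    kb_correct_per_rt_constant = correct_per_rt[1],
    kb_correct_per_rt_alternating = correct_per_rt[2],
    kb_correct_random = n_correct[3],
    kb_correct_per_rt_random = correct_per_rt[3]
  )
}

#' Extract the 28-feature vector of one session
#'
#' Concatenates the straight-line (9), sine (4), spiral (4) and keyboard
#' (11) features in registry order. Deterministic given the session.
#'
#' @param s A `pd_session`.
#' @inheritParams line_features
#' @return A 1-row tibble with the 28 registry columns.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(n_pd = 1, n_control = 1, seed = 1))
#' extract_features(cohort[[1]])
extract_features <- function(s, metric = "band") {
  if (!inherits(s, "pd_session")) rlang::abort("`s` must be a pd_session")
  out <- tryCatch(
    dplyr::bind_cols(
      line_features(s$mouse_trials$line, s$screen, metric = metric),
      curve_features(s$mouse_trials$sine, s$screen, metric = metric),
      curve_features(s$mouse_trials$spiral, s$screen, metric = metric),
      keyboard_features(unname(s$keyboard_trials))
    ),
    error = function(e) {
      rlang::abort(
        sprintf("feature extraction failed for session '%s'", s$session_id),
        parent = e
      )
    }
  )
  stopifnot(identical(names(out), feature_registry()$id))
  out
}

#' Build the cohort feature matrix
#'
#' One row per session in input order, the 28 registry features in order,
#' plus `session_id` and the label column `pd_status` (1 = PD). Sentinel
#' (`NA`) features are propagated as missing and reported with a message.
#'
#' @param cohort List of `pd_session` objects (e.g. from
#'   [simulate_cohort()]).
#' @inheritParams line_features
#' @return A tibble with `session_id`, `pd_status` and 28 feature columns.
#' @export
features_to_matrix <- function(cohort, metric = "band") {
  if (length(cohort) == 0) rlang::abort("`cohort` must contain at least one session")
  rows <- purrr::map(cohort, extract_features, metric = metric)
  out <- dplyr::bind_cols(
    tibble::tibble(
      session_id = vapply(cohort, function(s) s$session_id, character(1)),
      pd_status = as.integer(vapply(cohort, function(s) s$demographics$pd_status, logical(1)))
    ),
    dplyr::bind_rows(rows)
  )
  n_missing <- sum(is.na(dplyr::select(out, -"session_id", -"pd_status")))
  if (n_missing > 0) {
    rlang::inform(sprintf("%d missing feature value(s) propagated; impute at modeling time", n_missing))
  }
  out
}

#' The six-feature final model set
#'
#' The screening model's published feature list contains two aggregate
#' features that are not single registry rows: the average false-press count
#' over the three tapping trials and the total constant-key response time.
#' They are monotone transforms of registry features (`kb_false_total / 3`
#' and `10 * kb_rt_mean_constant` for a 10-prompt trial). This helper
#' materializes the six-feature set from a feature matrix.
#'
#' @param features A feature matrix from [features_to_matrix()].
#' @return The input tibble with columns `kb_false_avg` and
#'   `kb_rt_total_constant` added.
#' @export
final_model_features <- function(features) {
  dplyr::mutate(
    features,
    kb_false_avg = .data$kb_false_total / 3,
    kb_rt_total_constant = 10 * .data$kb_rt_mean_constant
  )
}

#' @rdname final_model_features
#' @export
final_feature_set <- function() {
  c("line_dev_mean", "sine_time_per_width", "spiral_time",
    "kb_false_avg", "kb_rt_total_constant", "kb_correct_per_rt_random")
}
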