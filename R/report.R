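#' Demographic summary tables
#'
#' Counts and integer-rounded percentages per age bracket, gender and race,
#' split into overall / PD / non-PD columns. Percentages are always taken
#' relative to the overall cohort size (so the PD and non-PD shares of a
#' row sum to the overall share); exact fractions are kept alongside the
#' rounded ones. Ages outside the fixed brackets (40-49 through 80-90) fall
#' into an `"other"` bucket with a warning; unspecified ages are excluded
#' from the mean/SD.
#'
#' @param cohort List of `pd_session` objects.
#' @return A `pd_demographics_summary`: list of tibbles `age`, `gender`,
#'   `race` (columns `level`, `n_overall`, `pct_overall`, `n_pd`, `pct_pd`,
#'   `n_control`, `pct_control`, plus exact fractions) and `age_stats`
#'   (per-group n, mean, sd of age).
#' @export
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(n_pd = 3, n_control = 3, seed = 2))
#' summarize_demographics(cohort)$age
summarize_demographics <- function(cohort) {
  if (length(cohort) == 0) rlang::abort("`cohort` must contain at least one session")
  dem <- purrr::map_dfr(cohort, function(s) {
    d <- s$demographics
    tibble::tibble(pd_status = d$pd_status, age = d$age,
                   gender = d$gender, race = d$race)
  })
  n_total <- nrow(dem)
  brackets <- c("40-49", "50-59", "60-69", "70-79", "80-90")
  bracket_of <- function(age) {
    if (is.na(age)) return("unspecified")
    lo <- c(40, 50, 60, 70, 80); hi <- c(49, 59, 69, 79, 90)
    hit <- which(age >= lo & age <= hi)
    if (length(hit) == 0) {
      rlang::warn(sprintf("age %d outside the reporting brackets; counted as 'other'", age))
      return("other")
    }
    brackets[hit]
  }
  dem$age_bracket <- vapply(dem$age, bracket_of, character(1))

  count_table <- function(values, levels) {
    lv <- union(levels, unique(values))
    tab <- function(keep) {
      counts <- table(factor(values[keep], levels = lv))
      as.integer(counts[lv])
    }
    out <- tibble::tibble(
      level = lv,
      n_overall = tab(rep(TRUE, n_total)),
      n_pd = tab(dem$pd_status),
      n_control = tab(!dem$pd_status)
    )
    for (col in c("overall", "pd", "control")) {
      n <- out[[paste0("n_", col)]]
      out[[paste0("frac_", col)]] <- n / n_total
      out[[paste0("pct_", col)]] <- as.integer(round(100 * n / n_total))
    }
    # drop empty optional levels, keep canonical ones
    out[out$n_overall > 0 | out$level %in% levels, ]
  }

  age_stats <- purrr::map_dfr(
    list(overall = rep(TRUE, n_total), pd = dem$pd_status, control = !dem$pd_status),
    function(keep) {
      a <- dem$age[keep]
      tibble::tibble(n = sum(keep), n_age_known = sum(!is.na(a)),
                     mean_age = mean(a, na.rm = TRUE),
                     sd_age = stats::sd(a, na.rm = TRUE))
    },
    .id = "group"
  )

  structure(
    list(
      age = count_table(dem$age_bracket, brackets),
      gender = count_table(dem$gender, c("male", "female", "other", "unspecified")),
      race = count_table(dem$race, c("white", "asian", "american_indian_alaska_native",
                                     "other", "unspecified")),
      age_stats = age_stats,
      n = n_total
    ),
    class = "pd_demographics_summary"
  )
}

#' @export
print.pd_demographics_summary <- function(x, ...) {
  cat(sprintf("<pd_demographics_summary> N = %d\n", x$n))
  print(x$age)
  invisible(x)
}

# ribbon outline polygon: centerline offset +/- half-width along the normal
ribbon_polygon <- function(spec, screen, n = 512) {
  cl <- instantiate_path(spec, screen, n = n)
  hw <- ribbon_half_width(spec, screen)
  tx <- c(diff(cl$x), 0) + c(0, diff(cl$x))
  ty <- c(diff(cl$y), 0) + c(0, diff(cl$y))
  nrm <- sqrt(tx^2 + ty^2)
  nx <- -ty / nrm
  ny <- tx / nrm
  tibble::tibble(
    x = c(cl$x + hw * nx, rev(cl$x - hw * nx)),
    y = c(cl$y + hw * ny, rev(cl$y - hw * ny))
  )
}

#' Reconstruct a session's traces as a figure
#'
#' Redraws each tracing trial from the logged data: the ribbon outline, the
#' centerline, and the sampled cursor polyline with inside/outside samples
#' distinguished by color. Axes are in screen pixels with the y axis
#' reversed to match screen coordinates. Output is deterministic for a fixed
#' session.
#'
#' @param s A `pd_session`.
#' @param shapes Which trials to draw (default all three).
#' @return A ggplot object, faceted by shape.
#' @export
plot_traces <- function(s, shapes = c("line", "sine", "spiral")) {
  if (!inherits(s, "pd_session")) rlang::abort("`s` must be a pd_session")
  shapes <- match.arg(shapes, several.ok = TRUE)
  ribbons <- purrr::map_dfr(shapes, function(sh) {
    dplyr::mutate(ribbon_polygon(s$mouse_trials[[sh]]$spec, s$screen), shape = sh)
  })
  centers <- purrr::map_dfr(shapes, function(sh) {
    cl <- instantiate_path(s$mouse_trials[[sh]]$spec, s$screen)
    tibble::tibble(x = cl$x, y = cl$y, shape = sh)
  })
  traces <- purrr::map_dfr(shapes, function(sh) {
    dplyr::mutate(s$mouse_trials[[sh]]$samples, shape = sh)
  })
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = ribbons, ggplot2::aes(x = .data$x, y = .data$y),
      fill = "grey85", color = "grey60", linewidth = 0.2
    ) +
    ggplot2::geom_path(
      data = centers, ggplot2::aes(x = .data$x, y = .data$y),
      color = "grey40", linetype = "dashed", linewidth = 0.3
    ) +
    ggplot2::geom_path(
      data = traces, ggplot2::aes(x = .data$x, y = .data$y),
      color = "steelblue", linewidth = 0.4
    ) +
    ggplot2::geom_point(
      data = traces,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$inside), size = 1
    ) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "forestgreen", `FALSE` = "firebrick"),
      name = "inside ribbon"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~shape, scales = "free") +
    ggplot2::labs(
      title = sprintf("Trace reconstruction: %s", s$session_id),
      x = "x (px)", y = "y (px)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_traces
#' @param object A `pd_session`.
#' @param ... Passed to [plot_traces()].
#' @method autoplot pd_session
#' @export
autoplot.pd_session <- function(object, ...) {
  plot_traces(object, ...)
}

#' Per-run metric plot of an evaluation report
#'
#' @param object A `pd_eval_report`.
#' @param ... Unused.
#' @return A ggplot object: per-run metric values with mean bars.
#' @method autoplot pd_eval_report
#' @export
autoplot.pd_eval_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$runs, c("auc", "balanced_accuracy", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6, color = "steelblue") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          color = "black", linewidth = 0.3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      title = sprintf("%s, %d features, %d runs", object$config$model_family,
                      length(object$features), object$config$n_runs),
      x = NULL, y = "metric value"
    ) +
    ggplot2::theme_minimal()
}
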