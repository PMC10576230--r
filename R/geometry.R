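#' Screen geometry
#'
#' Records the pixel dimensions of the participant's device. Stimuli are
#' defined as fractions of these dimensions so the same test adapts to any
#' screen.
#'
#' @param width,height Screen dimensions in pixels (>= 1).
#' @return A `screen_geometry` object (list with `width` and `height`).
#' @export
#' @examples
#' screen_geometry(1280, 800)
screen_geometry <- function(width, height) {
  for (v in list(width, height)) {
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v) || v < 1) {
      rlang::abort("screen dimensions must be single finite numbers >= 1 pixel")
    }
  }
  structure(
    list(width = as.integer(round(width)), height = as.integer(round(height))),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px\n", x$width, x$height))
  invisible(x)
}

#' Tracing stimulus specification
#'
#' A tracing stimulus is a parametric centerline (straight line, sine wave,
#' or Archimedean spiral) surrounded by a ribbon of fixed half-width that the
#' participant tries to keep the cursor inside. All parameters are fractions
#' of the screen dimensions, never absolute pixels, so the stimulus occupies
#' the same share of any display.
#'
#' Screen coordinates are 0-based with y increasing downward (the web canvas
#' convention of the capture client).
#'
#' @param shape One of `"line"`, `"sine"`, `"spiral"`.
#' @param margin_frac Horizontal margin at each end, as a fraction of screen
#'   width (and, for the spiral, of the limiting dimension). Must be < 0.5.
#' @param base_y_frac Vertical anchor of the centerline as a fraction of
#'   screen height (line and sine).
#' @param amplitude_frac Sine amplitude as a fraction of screen height.
#' @param n_periods Number of full sine periods across the trace.
#' @param n_turns Number of full spiral turns.
#' @param half_width_frac Ribbon half-width as a fraction of screen height.
#' @return A `path_spec` object.
#' @export
#' @examples
#' path_spec("sine")
#' path_spec("spiral", n_turns = 4)
path_spec <- function(shape = c("line", "sine", "spiral"),
                      margin_frac = 0.1,
                      base_y_frac = 0.5,
                      amplitude_frac = 0.2,
                      n_periods = 2,
                      n_turns = 3,
                      half_width_frac = 0.025) {
  shape <- rlang::arg_match(shape)
  frac_ok <- function(v) length(v) == 1L && is.numeric(v) && is.finite(v) && v > 0 && v < 1
  if (!frac_ok(margin_frac) || margin_frac >= 0.5) {
    rlang::abort("`margin_frac` must be in (0, 0.5)")
  }
  if (!frac_ok(base_y_frac)) rlang::abort("`base_y_frac` must be in (0, 1)")
  if (!frac_ok(amplitude_frac)) rlang::abort("`amplitude_frac` must be in (0, 1)")
  if (!frac_ok(half_width_frac)) rlang::abort("`half_width_frac` must be in (0, 1)")
  if (n_periods < 1 || n_periods != round(n_periods)) {
    rlang::abort("`n_periods` must be a positive integer")
  }
  if (n_turns < 1 || n_turns != round(n_turns)) {
    rlang::abort("`n_turns` must be a positive integer")
  }
  # ribbon containment: the band around the centerline must stay on screen
  amp <- if (shape == "sine") amplitude_frac else 0
  if (shape != "spiral") {
    if (base_y_frac - amp - half_width_frac < 0 ||
        base_y_frac + amp + half_width_frac > 1) {
      rlang::abort("ribbon extends beyond the screen: reduce amplitude_frac, base_y_frac or half_width_frac")
    }
  }
  structure(
    list(
      shape = shape, margin_frac = margin_frac, base_y_frac = base_y_frac,
      amplitude_frac = amplitude_frac, n_periods = as.integer(n_periods),
      n_turns = as.integer(n_turns), half_width_frac = half_width_frac
    ),
    class = "path_spec"
  )
}

#' @export
print.path_spec <- function(x, ...) {
  cat(sprintf("<path_spec> shape=%s margin=%.3f half_width=%.3f\n",
              x$shape, x$margin_frac, x$half_width_frac))
  invisible(x)
}

#' Ribbon half-width in pixels
#'
#' @param spec A [path_spec()].
#' @param screen A [screen_geometry()].
#' @return Half-width of the ribbon in pixels.
#' @export
ribbon_half_width <- function(spec, screen) {
  check_spec_screen(spec, screen)
  spec$half_width_frac * screen$height
}

check_spec_screen <- function(spec, screen) {
  if (!inherits(spec, "path_spec")) rlang::abort("`spec` must be a path_spec")
  if (!inherits(screen, "screen_geometry")) {
    rlang::abort("`screen` must be a screen_geometry")
  }
  invisible(TRUE)
}

# Closed-form pixel parameters of a spec instantiated on a screen.
# line/sine: x0, x1, y0, amp (px), n_periods
# spiral:    cx, cy, b (px/radian), theta_max; built so that the outermost
#            radius plus the ribbon half-width equals min(W,H)*(0.5 - margin).
path_params <- function(spec, screen) {
  check_spec_screen(spec, screen)
  W <- screen$width
  H <- screen$height
  hw <- spec$half_width_frac * H
  if (spec$shape == "spiral") {
    theta_max <- 2 * pi * spec$n_turns
    r_max <- min(W, H) * (0.5 - spec$margin_frac) - hw
    if (r_max <= 0) rlang::abort("spiral ribbon does not fit on this screen")
    list(
      shape = "spiral", cx = W / 2, cy = H / 2,
      b = r_max / theta_max, theta_max = theta_max, half_width = hw
    )
  } else {
    list(
      shape = spec$shape,
      x0 = spec$margin_frac * W, x1 = (1 - spec$margin_frac) * W,
      y0 = spec$base_y_frac * H,
      amp = if (spec$shape == "sine") spec$amplitude_frac * H else 0,
      n_periods = spec$n_periods, half_width = hw
    )
  }
}

#' Sample a stimulus centerline
#'
#' Instantiates a [path_spec()] on a screen and samples its centerline at
#' `n` points, with the cumulative chord-length fraction attached.
#'
#' Closed forms, in pixels: the line runs horizontally from
#' `(margin*W, base_y*H)` to `((1-margin)*W, base_y*H)`; the sine is
#' `y(x) = base_y*H - amplitude*H * sin(2*pi*n_periods*(x-x0)/(x1-x0))` over
#' the same x-range (minus because screen y grows downward); the spiral is
#' Archimedean, `r = b*theta` for `theta` in `[0, 2*pi*n_turns]`, centered on
#' the screen, with `b` chosen so the outermost radius plus the ribbon
#' half-width equals `min(W, H) * (0.5 - margin_frac)`.
#'
#' @param spec A [path_spec()].
#' @param screen A [screen_geometry()].
#' @param n Number of sample points (>= 256).
#' @return A tibble with columns `x`, `y` (pixels) and `arclength_frac`
#'   (non-decreasing, in \[0, 1\]), with the pixel-space parameter record in
#'   attribute `"params"`.
#' @export
#' @examples
#' cl <- instantiate_path(path_spec("line"), screen_geometry(1000, 800))
#' head(cl)
instantiate_path <- function(spec, screen, n = 512) {
  check_spec_screen(spec, screen)
  n <- max(as.integer(n), 256L)
  p <- path_params(spec, screen)
  if (spec$shape == "spiral") {
    theta <- seq(0, p$theta_max, length.out = n)
    r <- p$b * theta
    x <- p$cx + r * cos(theta)
    y <- p$cy + r * sin(theta)
  } else {
    x <- seq(p$x0, p$x1, length.out = n)
    y <- centerline_y(x, p)
  }
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  out <- tibble::tibble(x = x, y = y, arclength_frac = s / s[length(s)])
  attr(out, "params") <- p
  class(out) <- c("pd_centerline", class(out))
  out
}

# y of the line/sine centerline at horizontal position x (pixel params p)
centerline_y <- function(x, p) {
  if (p$shape == "line") {
    rep(p$y0, length(x))
  } else {
    p$y0 - p$amp * sin(2 * pi * p$n_periods * (x - p$x0) / (p$x1 - p$x0))
  }
}

#' Signed vertical deviation from a line or sine centerline
#'
#' The signed vertical distance from cursor samples to the stimulus
#' centerline at the sample's horizontal position. Positive values are below
#' the centerline in screen coordinates (y grows downward). Sample x values
#' outside the path's horizontal range are clamped to the nearest end, since
#' the test cannot prevent overshoot.
#'
#' @param x,y Sample coordinates in pixels (vectors of equal length).
#' @param spec A [path_spec()] with shape `"line"` or `"sine"`.
#' @param screen A [screen_geometry()].
#' @return Signed deviations in pixels.
#' @export
#' @examples
#' vertical_deviation(500, 410, path_spec("line"), screen_geometry(1000, 800))
vertical_deviation <- function(x, y, spec, screen) {
  check_spec_screen(spec, screen)
  if (spec$shape == "spiral") {
    rlang::abort("vertical deviation is undefined for the spiral; use radial_deviation()")
  }
  stopifnot(length(x) == length(y))
  p <- path_params(spec, screen)
  xc <- pmin(pmax(x, p$x0), p$x1)
  y - centerline_y(xc, p)
}

#' Radial deviation from the spiral centerline
#'
#' Converts a sample to polar coordinates about the spiral center and returns
#' the distance, measured radially, to the nearest spiral arm: the minimum
#' over arm indices k of `|r - b*(theta + 2*pi*k)|`, restricted to arm angles
#' within `[0, 2*pi*n_turns]`.
#'
#' @inheritParams vertical_deviation
#' @param spec A [path_spec()] with shape `"spiral"`.
#' @return Non-negative deviations in pixels.
#' @export
radial_deviation <- function(x, y, spec, screen) {
  check_spec_screen(spec, screen)
  if (spec$shape != "spiral") {
    rlang::abort("radial deviation is defined only for the spiral")
  }
  stopifnot(length(x) == length(y))
  p <- path_params(spec, screen)
  dx <- x - p$cx
  dy <- y - p$cy
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) %% (2 * pi)
  ks <- 0:ceiling(p$theta_max / (2 * pi))
  d <- rep(Inf, length(x))
  for (k in ks) {
    ang <- theta + 2 * pi * k
    ok <- ang <= p$theta_max + 1e-9
    d[ok] <- pmin(d[ok], abs(r[ok] - p$b * ang[ok]))
  }
  d
}

# Minimum Euclidean distance from points to the piecewise-linear centerline
# (projection onto each segment of the sampled polyline).
dist_to_centerline <- function(x, y, cl) {
  ax <- cl$x[-nrow(cl)]; ay <- cl$y[-nrow(cl)]
  bx <- cl$x[-1L];       by <- cl$y[-1L]
  ex <- bx - ax; ey <- by - ay
  len2 <- ex^2 + ey^2
  len2[len2 == 0] <- 1e-12
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    t <- ((x[i] - ax) * ex + (y[i] - ay) * ey) / len2
    t <- pmin(pmax(t, 0), 1)
    out[i] <- sqrt(min((x[i] - (ax + t * ex))^2 + (y[i] - (ay + t * ey))^2))
  }
  out
}

#' Ribbon membership of cursor samples
#'
#' Decides whether cursor samples lie inside the stimulus ribbon. Two metric
#' conventions are available:
#'
#' * `"band"` (default): vertical band for line and sine
#'   (`|vertical_deviation| <= half_width`), radial band for the spiral
#'   (`radial_deviation <= half_width`, plus a guard that the sample lies
#'   within 1.5 half-widths of the sampled centerline, which protects the
#'   spiral-center degeneracy where arm angles collapse).
#' * `"euclidean"`: true Euclidean distance to the centerline polyline
#'   `<= half_width`. Used mainly for cross-checking against brute-force
#'   nearest-point oracles.
#'
#' The two conventions agree exactly for the horizontal line and differ near
#' the ribbon boundary for curved shapes by the metric convention (a vertical
#' band is wider than a Euclidean band wherever the centerline is steep).
#'
#' @inheritParams vertical_deviation
#' @param spec A [path_spec()].
#' @param metric Membership convention, `"band"` or `"euclidean"`.
#' @param centerline_n Sampling density of the centerline polyline used for
#'   the Euclidean metric and the spiral guard.
#' @return Logical vector, `TRUE` for samples inside the ribbon.
#' @export
#' @examples
#' scr <- screen_geometry(1000, 800)
#' is_inside_ribbon(500, 405, path_spec("line"), scr)
is_inside_ribbon <- function(x, y, spec, screen,
                             metric = c("band", "euclidean"),
                             centerline_n = 2048) {
  metric <- rlang::arg_match(metric)
  check_spec_screen(spec, screen)
  stopifnot(length(x) == length(y))
  hw <- ribbon_half_width(spec, screen)
  if (metric == "euclidean") {
    cl <- instantiate_path(spec, screen, n = centerline_n)
    return(dist_to_centerline(x, y, cl) <= hw)
  }
  if (spec$shape == "spiral") {
    inside <- radial_deviation(x, y, spec, screen) <= hw
    if (any(inside)) {
      cl <- instantiate_path(spec, screen, n = centerline_n)
      near <- dist_to_centerline(x[inside], y[inside], cl) <= 1.5 * hw
      inside[inside] <- near
    }
    inside
  } else {
    abs(vertical_deviation(x, y, spec, screen)) <= hw
  }
}

#' Default stimulus set
#'
#' The three tracing stimuli of the test battery, in canonical order:
#' straight line, sine wave, spiral.
#'
#' @param half_width_frac Ribbon half-width fraction shared by all three.
#' @return Named list of three [path_spec()] objects.
#' @export
default_path_specs <- function(half_width_frac = 0.025) {
  list(
    line   = path_spec("line",   half_width_frac = half_width_frac),
    sine   = path_spec("sine",   half_width_frac = half_width_frac),
    spiral = path_spec("spiral", half_width_frac = half_width_frac)
  )
}
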