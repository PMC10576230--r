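test_that("line and sine centerlines match their closed forms", {
  scr <- screen_geometry(1000, 800)

  cl <- instantiate_path(path_spec("line"), scr)
  expect_equal(c(cl$x[1], cl$y[1]), c(100, 400))
  expect_equal(c(cl$x[nrow(cl)], cl$y[nrow(cl)]), c(900, 400))
  expect_true(all(diff(cl$arclength_frac) >= 0))
  expect_equal(range(cl$arclength_frac), c(0, 1))

  # sine: y anchored at base at the start, peak of 0.2*H = 160 px above the
  # base at the quarter-period x (sin = 1, screen y grows downward)
  sp <- path_spec("sine")
  expect_equal(vertical_deviation(100, 400, sp, scr), 0)
  x_quarter <- 100 + 800 / 8
  expect_equal(vertical_deviation(x_quarter, 400 - 160, sp, scr), 0)
})

test_that("spiral sizing follows the margin rule", {
  scr <- screen_geometry(1000, 1000)
  sp <- path_spec("spiral")
  cl <- instantiate_path(sp, scr)
  p <- attr(cl, "params")
  r_outer <- max(sqrt((cl$x - p$cx)^2 + (cl$y - p$cy)^2))
  # outermost radius + ribbon half-width = min(W,H) * (0.5 - margin) = 400
  expect_equal(r_outer + ribbon_half_width(sp, scr), 400, tolerance = 1 / 400)
})

test_that("instantiation rejects invalid specs and screens", {
  expect_error(screen_geometry(0, 800), "screen dimensions")
  expect_error(path_spec("line", margin_frac = 0.6), "margin_frac")
  expect_error(path_spec("sine", amplitude_frac = 0.6), "beyond the screen")
  expect_error(path_spec("line", half_width_frac = 0), "half_width_frac")
})

test_that("vertical deviation is signed, clamped, and shape-guarded", {
  scr <- screen_geometry(1000, 800)
  line <- path_spec("line")
  expect_equal(vertical_deviation(500, 410, line, scr), 10)
  expect_equal(vertical_deviation(500, 390, line, scr), -10)
  # x outside the path range is clamped to the nearest end
  expect_equal(vertical_deviation(5000, 410, line, scr), 10)
  # sine quarter-period point: centerline y = 240, sample y = 300 -> +60
  expect_equal(vertical_deviation(100 + 800 / 8, 300, path_spec("sine"), scr), 60)
  expect_error(vertical_deviation(1, 1, path_spec("spiral"), scr), "radial_deviation")
})

test_that("vertical deviation is antisymmetric about the centerline", {
  scr <- screen_geometry(1200, 900)
  for (shape in c("line", "sine")) {
    sp <- path_spec(shape)
    p <- pdtrace:::path_params(sp, scr)
    x <- seq(p$x0, p$x1, length.out = 25)
    yc <- pdtrace:::centerline_y(x, p)
    d <- 37.5
    expect_equal(
      vertical_deviation(x, yc + d, sp, scr),
      -vertical_deviation(x, yc - d, sp, scr)
    )
  }
})

test_that("radial deviation measures distance to the nearest spiral arm", {
  scr <- screen_geometry(1000, 1000)
  sp <- path_spec("spiral")
  p <- pdtrace:::path_params(sp, scr)
  # on-curve point at theta = pi
  on <- c(p$cx + p$b * pi * cos(pi), p$cy + p$b * pi * sin(pi))
  expect_equal(radial_deviation(on[1], on[2], sp, scr), 0, tolerance = 1e-9)
  # spiral center lies on the theta = 0 arm end
  expect_equal(radial_deviation(p$cx, p$cy, sp, scr), 0)
  # midway between the first two arms at angle pi: r = 2*b*pi, gap b*pi
  mid <- c(p$cx + 2 * p$b * pi * cos(pi), p$cy + 2 * p$b * pi * sin(pi))
  expect_equal(radial_deviation(mid[1], mid[2], sp, scr), p$b * pi, tolerance = 1 / (p$b * pi))
  # the radial measure can never undercut the true (Euclidean) distance
  set.seed(7)
  th <- runif(40, pi, p$theta_max)
  rr <- p$b * th + runif(40, -p$b * pi, p$b * pi)
  x <- p$cx + rr * cos(th)
  y <- p$cy + rr * sin(th)
  rd <- radial_deviation(x, y, sp, scr)
  od <- oracle_dist(x, y, sp, scr)
  expect_true(all(od <= rd + 0.5))
  # on the outer arms (shallow pitch angle) the two measures coincide
  th_out <- runif(40, 3 * pi, p$theta_max)
  hw <- ribbon_half_width(sp, scr)
  rr_out <- p$b * th_out + runif(40, -hw, hw)
  x <- p$cx + rr_out * cos(th_out)
  y <- p$cy + rr_out * sin(th_out)
  expect_true(all(abs(radial_deviation(x, y, sp, scr) -
                        oracle_dist(x, y, sp, scr)) <= 1))
  expect_error(radial_deviation(1, 1, path_spec("line"), scr), "spiral")
})

test_that("every sampled centerline point is inside its own ribbon", {
  scr <- screen_geometry(1280, 800)
  for (sp in default_path_specs()) {
    cl <- instantiate_path(sp, scr)
    for (metric in c("band", "euclidean")) {
      expect_true(all(is_inside_ribbon(cl$x, cl$y, sp, scr, metric = metric)),
                  info = paste(sp$shape, metric))
    }
  }
})

test_that("band membership flips exactly at the half-width boundary", {
  scr <- screen_geometry(1000, 800)
  sp <- path_spec("line")
  hw <- ribbon_half_width(sp, scr)
  expect_true(is_inside_ribbon(500, 400 + hw, sp, scr))
  expect_false(is_inside_ribbon(500, 400 + hw + 1, sp, scr))
  # within the path's x-range the band and euclidean conventions coincide
  # for the horizontal line (outside it, the band clamps overshoot)
  set.seed(3)
  x <- runif(100, 100, 900)
  y <- runif(100, 0, 800)
  expect_equal(
    is_inside_ribbon(x, y, sp, scr, metric = "band"),
    is_inside_ribbon(x, y, sp, scr, metric = "euclidean")
  )
})

test_that("euclidean membership agrees with a dense nearest-point oracle", {
  scr <- screen_geometry(1280, 800)
  set.seed(11)
  for (sp in default_path_specs()) {
    hw <- ribbon_half_width(sp, scr)
    x <- runif(200, 0, scr$width)
    y <- runif(200, 0, scr$height)
    d <- oracle_dist(x, y, sp, scr)
    clear <- abs(d - hw) > hw / 4  # exclude the boundary band
    got <- is_inside_ribbon(x[clear], y[clear], sp, scr, metric = "euclidean")
    expect_equal(got, d[clear] <= hw, info = sp$shape)
  }
})

test_that("centerlines scale equivariantly with the screen", {
  scr1 <- screen_geometry(800, 600)
  scr2 <- screen_geometry(1600, 1200)
  for (sp in default_path_specs()) {
    cl1 <- instantiate_path(sp, scr1, n = 300)
    cl2 <- instantiate_path(sp, scr2, n = 300)
    expect_equal(cl2$x, 2 * cl1$x, tolerance = 1e-12, info = sp$shape)
    expect_equal(cl2$y, 2 * cl1$y, tolerance = 1e-12, info = sp$shape)
    expect_equal(cl2$arclength_frac, cl1$arclength_frac, info = sp$shape)
  }
})
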