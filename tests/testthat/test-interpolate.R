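test_that("the linear interpolant follows the segment formula", {
  expect_equal(linear_interpolant(c(2, 4), 1.5), 3)
  expect_equal(linear_interpolant(c(5, 5, 5), 2.7), 5)
  expect_equal(linear_interpolant(c(0, 10, 0), 1.25), 2.5)
  expect_equal(linear_interpolant(c(1, 7), c(1, 2)), c(1, 7))  # exact at knots
  expect_error(linear_interpolant(c(1, 2), 2.1), "extrapolation")
  expect_error(linear_interpolant(c(1, 2), 0.9), "extrapolation")
})

test_that("natural spline second derivatives solve the continuity system", {
  # straight-line data: all second derivatives vanish
  m <- fit_cubic_spline(3 + 2 * (1:7), "natural")$m
  expect_equal(m, rep(0, 7), tolerance = 1e-12)
  # y = (0,1,0): single interior equation (2/3) M_2 = -2  =>  M = (0,-3,0)
  expect_equal(fit_cubic_spline(c(0, 1, 0), "natural")$m, c(0, -3, 0))
})

test_that("evaluate_spline reproduces knots and the hand-solved value", {
  s <- fit_cubic_spline(c(0, 1, 0), "natural")
  expect_equal(evaluate_spline(s, 1:3), c(0, 1, 0))
  expect_equal(evaluate_spline(s, 1.5), 0.6875)
  # splines reproduce straight lines exactly at arbitrary points
  lin <- fit_cubic_spline(1 + 0.5 * (1:6), "natural")
  xs <- seq(1, 6, by = 0.23)
  expect_equal(evaluate_spline(lin, xs), 1 + 0.5 * xs, tolerance = 1e-12)
  expect_error(evaluate_spline(s, 3.5), "extrapolation")
})

test_that("periodic splines match first and second derivatives at the ends", {
  for (y in list(c(1, 0, 1), c(0, 2, -1, 3, 0), cos(2 * pi * (0:8) / 8))) {
    s <- fit_cubic_spline(y, "periodic")
    L <- length(y)
    m <- s$m
    # closed-form end slopes of the piecewise cubic (unit knot spacing)
    d1_left <- (y[2] - y[1]) - (2 * m[1] + m[2]) / 6
    d1_right <- (y[L] - y[L - 1]) + (m[L - 1] + 2 * m[L]) / 6
    expect_lt(abs(d1_left - d1_right), 1e-10)
    expect_lt(abs(m[1] - m[L]), 1e-10)  # S'' continuity
  }
  # hand-solved cyclic system for y = (1, 0, 1)
  expect_equal(fit_cubic_spline(c(1, 0, 1), "periodic")$m, c(-6, 6, -6))
})

test_that("periodic boundary enforces equal endpoints unless coerced", {
  expect_error(fit_cubic_spline(c(0, 1, 2), "periodic"), "coerce")
  expect_warning(s <- fit_cubic_spline(c(0, 1, 2), "periodic", coerce = TRUE),
                 "coerced")
  expect_equal(s$y, c(0, 1, 0))
})

test_that("fmm end cubics carry the curvature of the outer four points", {
  # data on an exact cubic: the fmm spline must reproduce it everywhere
  f <- function(x) 2 - x + 0.5 * x^2 - 0.25 * x^3
  y <- f(1:8)
  s <- fit_cubic_spline(y, "fmm")
  xs <- seq(1, 8, by = 0.17)
  expect_equal(evaluate_spline(s, xs), f(xs), tolerance = 1e-9)
  # ... which natural boundaries cannot do
  sn <- fit_cubic_spline(y, "natural")
  expect_gt(max(abs(evaluate_spline(sn, xs) - f(xs))), 1e-3)
})

test_that("fmm falls back for short inputs with a warning", {
  expect_warning(s3 <- fit_cubic_spline(c(0, 1, 0), "fmm"), "falling back")
  expect_equal(s3$boundary, "natural")
  expect_equal(s3$m, c(0, -3, 0))
  expect_warning(s2 <- fit_cubic_spline(c(0, 1), "fmm"), "falling back")
  expect_equal(s2$m, c(0, 0))
})

test_that("all three solvers agree with the dense brute-force system", {
  set.seed(101)
  for (bd in c("natural", "periodic", "fmm")) {
    for (r in 1:25) {
      L <- sample(4:12, 1)
      y <- rnorm(L)
      if (bd == "periodic") y[L] <- y[1]
      oracle <- dense_spline_oracle(y, bd)
      model <- fit_cubic_spline(y, bd)
      xs <- c(1, L, runif(40, 1, L))
      expect_equal(evaluate_spline(model, xs), oracle(xs), tolerance = 1e-9)
    }
  }
})

test_that("solvers agree with stats::splinefun as an independent reference", {
  set.seed(202)
  for (bd in c("natural", "periodic", "fmm")) {
    for (r in 1:10) {
      L <- sample(4:20, 1)
      y <- rnorm(L)
      if (bd == "periodic") y[L] <- y[1]
      ref <- stats::splinefun(seq_len(L), y, method = bd)
      model <- fit_cubic_spline(y, bd)
      xs <- seq(1, L, length.out = 77)
      expect_equal(evaluate_spline(model, xs), ref(xs), tolerance = 1e-10)
    }
  }
})

test_that("resample validates its arguments", {
  expect_error(resample(c(1, 2, 3), 1), "dims")
  expect_error(resample(c(1, 2, 3), 4.5), "dims")
  expect_error(resample(2, 5), "length >= 2")
  expect_error(resample(c(1, NA, 3), 5), "finite")
  expect_error(resample(1:5, 7, method = "cubic"),
               "linear, spline, fmm, natural, periodic")
})

test_that("resample refines affine data onto the affine target grid", {
  expect_equal(resample(c(0, 1, 2, 3), 7), c(0, 0.5, 1, 1.5, 2, 2.5, 3))
  # affine input stays exactly affine under every method (periodic: constant)
  y <- 2 + 0.75 * (1:9)
  grid <- 1 + (0:19) * 8 / 19
  for (m in c("linear", "spline", "fmm", "natural"))
    expect_equal(resample(y, 20, method = m), 2 + 0.75 * grid,
                 tolerance = 1e-12)
  expect_equal(resample(rep(1.5, 9), 20, method = "periodic"), rep(1.5, 20))
})

test_that("knot reproduction: resampling to the input length is the identity", {
  set.seed(303)
  for (r in 1:20) {
    L <- sample(2:40, 1)
    y <- rnorm(L)
    for (m in c("linear", "spline", "fmm", "natural")) {
      out <- suppressWarnings(resample(y, L, method = m))
      expect_equal(out, y, tolerance = 1e-10)
    }
    yp <- y; yp[L] <- yp[1]
    expect_equal(resample(yp, L, method = "periodic"), yp, tolerance = 1e-10)
  }
})

test_that("endpoints are preserved for every method and target length", {
  set.seed(404)
  for (r in 1:15) {
    L <- sample(4:30, 1)
    D <- sample(2:60, 1)
    y <- rnorm(L)
    for (m in c("linear", "spline", "fmm", "natural")) {
      out <- resample(y, D, method = m)
      expect_identical(out[1], y[1])
      expect_identical(out[D], y[L])
    }
    yp <- y; yp[L] <- yp[1]
    outp <- resample(yp, D, method = "periodic")
    expect_identical(outp[1], yp[1])
    expect_identical(outp[D], yp[L])
  }
})

test_that("linear resampling never leaves the input range", {
  set.seed(505)
  for (r in 1:15) {
    y <- rnorm(sample(2:30, 1))
    out <- resample(y, sample(2:80, 1), method = "linear")
    expect_gte(min(out), min(y))
    expect_lte(max(out), max(y))
  }
})

test_that("resampling equals direct evaluation of the same interpolant", {
  set.seed(606)
  y <- rnorm(11)
  D <- 27
  grid <- 1 + (seq_len(D) - 1) * 10 / (D - 1)
  grid[D] <- 11
  expect_identical(resample(y, D, method = "natural"),
                   evaluate_spline(fit_cubic_spline(y, "natural"), grid))
  expect_identical(resample(y, D, method = "linear"),
                   linear_interpolant(y, grid))
})
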