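# The interpolation knots of an encoded sequence of length L sit at the
# integer positions x = 1..L (unit spacing).  All cubic splines below use
# the second-derivative (M) formulation: on interval [i, i+1], with
# t = x - i,
#
#   S(x) = y_i (1-t) + y_{i+1} t
#        + M_i/6 ((1-t)^3 - (1-t)) + M_{i+1}/6 (t^3 - t)
#
# C2 continuity at the interior knots gives the tridiagonal system
#   M_{i-1} + 4 M_i + M_{i+1} = 6 (y_{i+1} - 2 y_i + y_{i-1}),  i = 2..L-1,
# closed by two boundary rows depending on the boundary treatment.

#' Names of the supported interpolation methods
#'
#' `"linear"` (the default everywhere), `"spline"`, `"fmm"`, `"natural"`
#' and `"periodic"`. `"spline"` is an alias for `"fmm"`, the
#' Forsythe-Malcolm-Moler end condition; the package implements exactly
#' three distinct cubic boundary treatments (fmm, natural, periodic) plus
#' piecewise-linear interpolation.
#'
#' @return Character vector of the five accepted method names.
#' @export
interpolation_methods <- function() {
  c("linear", "spline", "fmm", "natural", "periodic")
}

match_method <- function(method) {
  if (!is.character(method) || length(method) != 1L ||
      !method %in% interpolation_methods())
    abort(sprintf("`method` must be one of: %s.",
                  paste(interpolation_methods(), collapse = ", ")))
  if (method == "spline") "fmm" else method
}

#' Evaluate the piecewise-linear interpolant of a vector
#'
#' The interpolant connects consecutive knots `(i, values[i])`,
#' `(i+1, values[i+1])` with straight segments; it is exact at the integer
#' knot positions and defined only on `[1, length(values)]` (no
#' extrapolation).
#'
#' @param values Numeric vector of knot values at positions `1..L`, `L >= 2`.
#' @param x Numeric vector of evaluation positions in `[1, L]`.
#' @return Numeric vector, `length(x)`.
#' @examples
#' linear_interpolant(c(2, 4), 1.5)   # 3
#' @export
linear_interpolant <- function(values, x) {
  L <- length(values)
  if (L < 2L) abort("`values` must have length >= 2.")
  if (!all(is.finite(values))) abort("`values` must be finite.")
  if (any(x < 1 | x > L))
    abort(sprintf("evaluation positions must lie in [1, %d]; no extrapolation.", L))
  i <- pmin(pmax(floor(x), 1L), L - 1L)
  t <- x - i
  values[i] * (1 - t) + values[i + 1L] * t
}

# Thomas algorithm for a tridiagonal system; a = sub-, b = main,
# c = super-diagonal (lengths n-1, n, n-1).  Direct solve, O(n).
solve_tridiag <- function(a, b, c, d) {
  n <- length(b)
  if (n == 1L) return(d / b)
  cp <- numeric(n - 1L); dp <- numeric(n)
  cp[1L] <- c[1L] / b[1L]
  dp[1L] <- d[1L] / b[1L]
  for (i in 2:n) {
    m <- b[i] - a[i - 1L] * cp[i - 1L]
    if (i < n) cp[i] <- c[i] / m
    dp[i] <- (d[i] - a[i - 1L] * dp[i - 1L]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

# Cyclic tridiagonal solve (corners alpha = A[1,n], beta = A[n,1]) via
# Sherman-Morrison rank-one update of the plain tridiagonal solve.
solve_cyclic_tridiag <- function(a, b, c, alpha, beta, d) {
  n <- length(b)
  if (n == 1L) return(d / b)
  if (n == 2L) {
    # corners collide with the off-diagonals; solve directly
    A <- matrix(c(b[1L], a[1L] + beta, c[1L] + alpha, b[2L]), 2L, 2L)
    return(as.numeric(solve(A, d)))
  }
  gamma <- -b[1L]
  bb <- b
  bb[1L] <- b[1L] - gamma
  bb[n] <- b[n] - alpha * beta / gamma
  x <- solve_tridiag(a, bb, c, d)
  u <- numeric(n); u[1L] <- gamma; u[n] <- alpha
  z <- solve_tridiag(a, bb, c, u)
  fact <- (x[1L] + beta * x[n] / gamma) / (1 + z[1L] + beta * z[n] / gamma)
  x - fact * z
}

#' Fit a cubic interpolating spline through an encoded sequence
#'
#' Solves for the second derivatives `M_1..M_L` of the piecewise cubic
#' through the knots `(i, values[i])`, `i = 1..L`, under one of three
#' boundary treatments:
#'
#' * `"natural"`: zero second derivative at both ends (`M_1 = M_L = 0`).
#' * `"periodic"`: equal first and second derivatives at the two endpoints;
#'   requires `values[1] == values[L]` (within `1e-9`), or `coerce = TRUE`
#'   to overwrite the last value with the first (with a warning).
#' * `"fmm"` (Forsythe-Malcolm-Moler): at each end, the spline's third
#'   derivative matches that of the single cubic passing exactly through
#'   the outermost four points, so the end pieces follow that exact cubic's
#'   curvature.
#'
#' The interior conditions form a tridiagonal (natural, fmm) or
#' cyclic-tridiagonal (periodic) linear system, solved directly with the
#' Thomas algorithm, the periodic case via Sherman-Morrison rank-one
#' update. `"fmm"` needs four points per end: with `L = 3` it falls back
#' to `"natural"`, with `L = 2` to the (linear) natural spline, each with
#' a warning.
#'
#' @param values Numeric knot values at positions `1..L`, `L >= 2`.
#' @param boundary `"natural"`, `"periodic"` or `"fmm"`.
#' @param coerce Periodic only: replace `values[L]` by `values[1]` instead
#'   of erroring when the endpoints differ.
#' @return An object of class `cubic_spline`: list with `x` (knot
#'   positions), `y` (knot values), `m` (second derivatives) and
#'   `boundary` (the treatment actually applied).
#' @seealso [evaluate_spline()], [resample()]
#' @examples
#' fit_cubic_spline(c(0, 1, 0), "natural")$m   # 0 -3 0
#' @export
fit_cubic_spline <- function(values, boundary = c("natural", "periodic", "fmm"),
                             coerce = FALSE) {
  boundary <- match.arg(boundary)
  y <- as.numeric(values)
  L <- length(y)
  if (L < 2L) abort("`values` must have length >= 2.")
  if (!all(is.finite(y))) abort("`values` must be finite.")

  if (boundary == "fmm" && L < 4L) {
    warn(sprintf(
      "fmm end conditions need 4 points per end; falling back to %s for length %d.",
      if (L == 3L) "'natural'" else "the linear (natural) spline", L))
    boundary <- "natural"
  }

  if (boundary == "periodic") {
    if (abs(y[1L] - y[L]) > 1e-9) {
      if (!coerce)
        abort(paste0("periodic boundary requires values[1] == values[L] ",
                     "(within 1e-9); set `coerce = TRUE` to overwrite the ",
                     "last value with the first."))
      warn("periodic boundary: last value coerced to equal the first.")
      y[L] <- y[1L]
    }
    m <- fit_periodic_m(y)
  } else {
    m <- fit_tridiag_m(y, boundary)
  }
  structure(list(x = seq_len(L), y = y, m = m, boundary = boundary),
            class = "cubic_spline")
}

# natural / fmm second derivatives via one tridiagonal solve over all L rows
fit_tridiag_m <- function(y, boundary) {
  L <- length(y)
  if (L == 2L) return(c(0, 0))  # both treatments reduce to the chord
  sub <- c(rep(1, L - 2L), 0)
  sup <- c(0, rep(1, L - 2L))
  dia <- c(1, rep(4, L - 2L), 1)
  rhs <- c(0, 6 * diff(y, differences = 2L), 0)
  if (boundary == "fmm") {
    # third derivative of the end cubics through the outer four points:
    # S''' = M_{i+1} - M_i on an end interval; the exact cubic's third
    # derivative is the third forward difference at unit spacing.
    sub[L - 1L] <- -1; dia[L] <- 1
    dia[1L] <- -1;     sup[1L] <- 1
    rhs[1L] <- y[4L] - 3 * y[3L] + 3 * y[2L] - y[1L]
    rhs[L]  <- y[L] - 3 * y[L - 1L] + 3 * y[L - 2L] - y[L - 3L]
  }
  solve_tridiag(sub, dia, sup, rhs)
}

# periodic second derivatives: unknowns M_1..M_{L-1}, M_L = M_1, cyclic system
fit_periodic_m <- function(y) {
  L <- length(y)
  if (L == 2L) return(c(0, 0))  # constant function
  n <- L - 1L
  yw <- y[-L]                         # y_1..y_{L-1}, wrap index 0 -> L-1
  nxt <- c(yw[-1L], yw[1L])
  prv <- c(yw[n], yw[-n])
  rhs <- 6 * (nxt - 2 * yw + prv)
  m <- solve_cyclic_tridiag(rep(1, n - 1L), rep(4, n), rep(1, n - 1L),
                            alpha = 1, beta = 1, d = rhs)
  c(m, m[1L])
}

#' Evaluate a fitted cubic spline
#'
#' Evaluates the piecewise cubic of a [fit_cubic_spline()] model at
#' positions within the knot range; knots are reproduced exactly and
#' extrapolation is refused.
#'
#' @param model A `cubic_spline` object.
#' @param x Numeric vector of positions in `[1, L]`.
#' @return Numeric vector of interpolant values, `length(x)`.
#' @examples
#' s <- fit_cubic_spline(c(0, 1, 0), "natural")
#' evaluate_spline(s, 1.5)   # 0.6875
#' @export
evaluate_spline <- function(model, x) {
  stopifnot(inherits(model, "cubic_spline"))
  L <- length(model$y)
  if (any(x < 1 | x > L))
    abort(sprintf("evaluation positions must lie in [1, %d]; no extrapolation.", L))
  i <- pmin(pmax(floor(x), 1L), L - 1L)
  t <- x - i
  u <- 1 - t
  y <- model$y; m <- model$m
  y[i] * u + y[i + 1L] * t +
    m[i] / 6 * (u^3 - u) + m[i + 1L] / 6 * (t^3 - t)
}

#' @export
print.cubic_spline <- function(x, ...) {
  cat(sprintf("<cubic_spline> %d knots, %s boundary\n", length(x$y), x$boundary))
  invisible(x)
}

#' Resample a numeric vector to a new length by interpolation
#'
#' Normalizes a vector of length `L` to length `dims`: an interpolant is
#' fitted through the knots `(1, values[1]) .. (L, values[L])` and
#' evaluated on the uniform target grid
#' `x_j = 1 + (j - 1) (L - 1) / (dims - 1)`, `j = 1..dims`, which spans
#' `[1, L]` inclusively. Both endpoints are therefore always preserved:
#' `out[1] == values[1]` and `out[dims] == values[L]`. With `dims == L`
#' the grid coincides with the knots and the input is returned exactly.
#'
#' @param values Numeric vector, length `L >= 2`.
#' @param dims Target length, `>= 2`.
#' @param method One of `"linear"` (default), `"spline"`, `"fmm"`,
#'   `"natural"`, `"periodic"` (see [interpolation_methods()]; `"spline"`
#'   is the fmm spline).
#' @param coerce Passed to [fit_cubic_spline()] for `"periodic"`.
#' @return Numeric vector of length `dims`.
#' @examples
#' resample(c(0, 1, 2, 3), 7)                 # refines the straight line
#' resample(rnorm(38), 35, method = "spline") # cubic length normalization
#' @export
resample <- function(values, dims, method = "linear", coerce = FALSE) {
  method <- match_method(method)
  L <- length(values)
  if (L < 2L) abort("`values` must have length >= 2.")
  if (!is.numeric(dims) || length(dims) != 1L || is.na(dims) || dims < 2L ||
      dims != as.integer(dims))
    abort("`dims` must be a single integer >= 2.")
  if (!all(is.finite(values))) abort("`values` must be finite.")
  dims <- as.integer(dims)
  grid <- 1 + (seq_len(dims) - 1) * (L - 1) / (dims - 1)
  grid[dims] <- L  # guard the last grid point against rounding drift
  if (method == "linear") {
    linear_interpolant(values, grid)
  } else {
    evaluate_spline(fit_cubic_spline(values, boundary = method, coerce = coerce),
                    grid)
  }
}
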