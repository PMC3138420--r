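# Brute-force cubic-spline oracle: assembles the full 4(L-1)-equation
# linear system in the per-interval polynomial coefficients
# p_i(t) = a_i + b_i t + c_i t^2 + d_i t^3, t = x - i in [0, 1], and solves
# it with a generic dense solver.  Independent of the tridiagonal /
# second-derivative path used by fit_cubic_spline().
dense_spline_oracle <- function(y, boundary = c("natural", "periodic", "fmm")) {
  boundary <- match.arg(boundary)
  L <- length(y)
  ni <- L - 1L
  n <- 4L * ni
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  col <- function(i, k) 4L * (i - 1L) + k  # k = 1..4 -> a,b,c,d of interval i
  row <- 0L
  put <- function(coefs, value) {
    row <<- row + 1L
    for (nm in names(coefs)) A[row, as.integer(nm)] <<- coefs[[nm]]
    rhs[row] <<- value
  }
  for (i in seq_len(ni)) {
    put(setNames(list(1), col(i, 1)), y[i])                       # p_i(0) = y_i
    put(setNames(list(1, 1, 1, 1), col(i, 1:4)), y[i + 1L])       # p_i(1) = y_{i+1}
  }
  for (i in seq_len(ni - 1L)) {
    put(setNames(list(1, 2, 3, -1), c(col(i, 2:4), col(i + 1L, 2))), 0)  # C1
    put(setNames(list(2, 6, -2), c(col(i, 3:4), col(i + 1L, 3))), 0)     # C2
  }
  if (boundary == "natural") {
    put(setNames(list(2), col(1L, 3)), 0)
    put(setNames(list(2, 6), col(ni, 3:4)), 0)
  } else if (boundary == "periodic") {
    stopifnot(abs(y[1L] - y[L]) < 1e-12)
    put(setNames(list(1, -1, -2, -3), c(col(1L, 2), col(ni, 2:4))), 0)  # S'
    put(setNames(list(2, -2, -6), c(col(1L, 3), col(ni, 3:4))), 0)      # S''
  } else { # fmm: S''' at each end = third difference of the outer 4 points
    stopifnot(L >= 4L)
    put(setNames(list(6), col(1L, 4)), y[4L] - 3 * y[3L] + 3 * y[2L] - y[1L])
    put(setNames(list(6), col(ni, 4)),
        y[L] - 3 * y[L - 1L] + 3 * y[L - 2L] - y[L - 3L])
  }
  coef <- solve(A, rhs)
  function(x) {
    i <- pmin(pmax(floor(x), 1L), ni)
    t <- x - i
    a <- coef[4 * (i - 1) + 1]; b <- coef[4 * (i - 1) + 2]
    c_ <- coef[4 * (i - 1) + 3]; d <- coef[4 * (i - 1) + 4]
    a + b * t + c_ * t^2 + d * t^3
  }
}

# Kyte-Doolittle hydropathy values, transcribed from the published scale,
# in canonical residue order.
KD_FIXTURE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Build one AAindex1 record as a character vector of lines.  `values` is a
# length-20 vector in the flat-file column order (row 1: A R N D C Q E G H I,
# row 2: L K M F P S T W Y V); character entries (e.g. "NA") are kept as is.
aaindex1_record <- function(accession, description, values) {
  fmt <- function(v) paste(sprintf("%7s", as.character(v)), collapse = " ")
  c(paste("H", accession),
    paste("D", description),
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    fmt(values[1:10]),
    fmt(values[11:20]),
    "//")
}
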