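# Cubic regression spline bases parameterized by function values at the
# knots.  With gamma the knot values and m the knot second derivatives,
# spline interpolation theory gives a banded linear system B m = D gamma;
# the design matrix and the curvature penalty  integral(f'')^2 =
# gamma' D' B^{-1} D gamma  both follow from it.  Two variants:
#
#  * natural ("cr"):  m_1 = m_k = 0 at the boundary knots;
#  * cyclic  ("cc"):  value, slope and curvature match at 0 and the
#    period, so the last knot is identified with the first and there are
#    k - 1 free coefficients.
#
# Knots are evenly spaced, which makes the cyclic wrap exact.

# banded system matrices for a natural cubic regression spline
crs_system <- function(knots) {
  k <- length(knots)
  h <- diff(knots)
  B <- matrix(0, k - 2, k - 2)
  D <- matrix(0, k - 2, k)
  for (i in seq_len(k - 2)) {
    B[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < k - 2) { B[i, i + 1] <- h[i + 1] / 6; B[i + 1, i] <- h[i + 1] / 6 }
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
  }
  Binv <- solve(B)
  list(Fmap = rbind(0, Binv %*% D, 0),     # gamma -> second derivatives
       S = t(D) %*% Binv %*% D)            # curvature penalty
}

# cyclic variant: n = k - 1 distinct knots, indices wrap
ccrs_system <- function(knots) {
  k <- length(knots)
  n <- k - 1
  h <- diff(knots)                         # h[j]: knot j -> j+1, j = 1..n
  B <- matrix(0, n, n)
  D <- matrix(0, n, n)
  for (j in seq_len(n)) {
    jm <- if (j == 1) n else j - 1
    jp <- if (j == n) 1 else j + 1
    B[j, j] <- (h[jm] + h[j]) / 3
    B[j, jm] <- B[j, jm] + h[jm] / 6
    B[j, jp] <- B[j, jp] + h[j] / 6
    D[j, j] <- -1 / h[jm] - 1 / h[j]
    D[j, jm] <- D[j, jm] + 1 / h[jm]
    D[j, jp] <- D[j, jp] + 1 / h[j]
  }
  Binv <- solve(B)
  list(Fmap = Binv %*% D, S = t(D) %*% Binv %*% D)
}

# Hermite-style design rows given the panel index and local coordinates
spline_rows <- function(x, knots, Fmap, cyclic) {
  k <- length(knots)
  ncoef <- if (cyclic) k - 1 else k
  n <- length(x)
  X <- matrix(0, n, ncoef)
  j <- findInterval(x, knots, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), k - 1L)
  h <- knots[j + 1] - knots[j]
  xr <- knots[j + 1] - x
  xl <- x - knots[j]
  am <- xr / h
  ap <- xl / h
  cm <- (xr^3 / h - h * xr) / 6
  cp <- (xl^3 / h - h * xl) / 6
  for (i in seq_len(n)) {
    ji <- j[i]
    jp <- if (cyclic && ji == ncoef) 1L else ji + 1L
    X[i, ji] <- X[i, ji] + am[i]
    X[i, jp] <- X[i, jp] + ap[i]
    X[i, ] <- X[i, ] + cm[i] * Fmap[if (cyclic) ji else ji, ] +
      cp[i] * Fmap[if (cyclic) jp else ji + 1L, ]
  }
  X
}

#' Cyclic cubic regression spline basis
#'
#' Evaluates the cyclic cubic regression spline basis on `k` evenly
#' spaced knots over `[0, period]` (the two endpoints identified, so
#' there are `k - 1` basis coefficients).  Any represented function and
#' its first two derivatives match at 0 and `period`.  The curvature
#' penalty matrix is attached as attribute `"S"` and the knots as
#' `"knots"`.
#'
#' @param x covariate values (wrapped into `[0, period)` by modulo).
#' @param period cycle length (`> 0`), e.g. 24 for hour of day.
#' @param k number of knots (`>= 4`).
#' @return design matrix with `length(x)` rows and `k - 1` columns.
#' @export
cyclic_basis <- function(x, period, k = 10) {
  if (k < 4) stop("'k' must be at least 4")
  stopifnot(period > 0, all(is.finite(x)))
  knots <- seq(0, period, length.out = k)
  sys <- ccrs_system(knots)
  X <- spline_rows(x %% period, knots, sys$Fmap, cyclic = TRUE)
  structure(X, S = sys$S, knots = knots, period = period)
}

# natural (non-cyclic) spline basis over the data range; out-of-range
# values are clamped to the boundary knots
natural_basis <- function(x, k = 10, range = NULL) {
  if (k < 4) stop("'k' must be at least 4")
  if (is.null(range)) range <- range(x)
  if (diff(range) <= 0) stop("covariate is constant; no spline basis")
  knots <- seq(range[1], range[2], length.out = k)
  sys <- crs_system(knots)
  xc <- pmin(pmax(x, range[1]), range[2])
  X <- spline_rows(xc, knots, sys$Fmap, cyclic = FALSE)
  structure(X, S = sys$S, knots = knots)
}
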