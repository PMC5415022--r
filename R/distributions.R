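# Count distributions used by the GARMA engine: Poisson inverse-Gaussian
# (PIG) and zero-inflated Poisson (ZIP), in the mean/dispersion
# parameterizations fixed by the model interface.

#' Poisson inverse-Gaussian probability mass function
#'
#' Mean--dispersion parameterization: `Y | Z ~ Poisson(mu * Z)` with
#' `Z ~ IG(1, shape = 1/sigma)`, so `E(Y) = mu` and
#' `Var(Y) = mu * (1 + sigma * mu)`.  The pmf is evaluated through its
#' modified-Bessel closed form
#' `P(y) = C(y) * K_{y - 1/2}(omega)` with `omega = sqrt(1 + 2*sigma*mu)/sigma`;
#' the half-integer-order Bessel factor is evaluated on the log scale by
#' a stable upward recurrence so that small dispersions (the Poisson
#' limit) and large counts stay finite.
#'
#' @param y vector of non-negative integer counts.
#' @param mu mean, `> 0`; scalar or vector recycled against `y`.
#' @param sigma dispersion, `>= 0`; `sigma = 0` falls back to the Poisson
#'   pmf (the analytic limit).
#' @param log if `TRUE` return log-probabilities.
#' @return vector of (log-)probabilities.
#' @export
dpig <- function(y, mu, sigma, log = FALSE) {
  n <- max(length(y), length(mu), length(sigma))
  y <- rep_len(y, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  if (any(mu <= 0)) stop("'mu' must be positive")
  if (any(sigma < 0)) stop("'sigma' must be non-negative")
  if (any(y < 0) || any(y != floor(y))) stop("'y' must be non-negative integers")
  out <- numeric(n)
  # Poisson limit: below ~1e-8 the Bessel form loses nothing but risks
  # overflow in the scaled Bessel factor, so switch analytically.
  pois <- sigma < 1e-8
  if (any(pois)) out[pois] <- dpois(y[pois], mu[pois], log = TRUE)
  if (any(!pois)) {
    yy <- y[!pois]; m <- mu[!pois]; s <- sigma[!pois]
    cfac <- sqrt(1 + 2 * s * m)
    omega <- cfac / s
    lbes <- log_besselK_half(omega, yy)
    out[!pois] <- yy * log(m) - lgamma(yy + 1) - 0.5 * log(2 * pi * s) +
      1 / s + log(2) - ((2 * yy - 1) / 2) * log(cfac) + lbes
  }
  if (log) out else exp(out)
}

# log K_{y - 1/2}(x), vectorized over (x, y) with y a non-negative
# integer.  Half-integer-order modified Bessel functions are elementary;
# the three-term upward recurrence K_{v+1} = (2v/x) K_v + K_{v-1} is
# stable for K and is run on the log scale so that orders in the hundreds
# (far beyond double overflow for the raw function) remain finite.
log_besselK_half <- function(x, y) {
  l0 <- 0.5 * log(pi / (2 * x)) - x      # order -1/2 (== order 1/2)
  l1 <- l0                               # order  1/2
  out <- ifelse(y == 0, l0, l1)
  ymax <- max(y)
  if (ymax >= 2) {
    for (j in 1:(ymax - 1)) {            # compute order j + 1/2
      v <- j - 0.5
      lnew <- l1 + log((2 * v) / x + exp(l0 - l1))
      l0 <- l1
      l1 <- lnew
      hit <- y == j + 1
      if (any(hit)) out[hit] <- lnew[hit]
    }
  }
  out
}

#' Poisson inverse-Gaussian cumulative distribution function
#'
#' @inheritParams dpig
#' @param q vector of quantiles (non-negative integers; non-integers are
#'   floored, as usual for a discrete cdf).
#' @return `P(Y <= q)`.
#' @export
ppig <- function(q, mu, sigma) {
  n <- max(length(q), length(mu), length(sigma))
  q <- rep_len(q, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  q <- floor(q)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (q[i] < 0) { out[i] <- 0; next }
    out[i] <- min(1, sum(dpig(0:q[i], mu[i], sigma[i])))
  }
  out
}

#' Inverse-Gaussian random draws
#'
#' Transformation-with-rejection sampler (Michael, Schucany & Haas) for the
#' inverse-Gaussian distribution with mean `mean` and shape `shape`
#' (variance `mean^3 / shape`).
#'
#' @param n number of draws.
#' @param mean distribution mean, `> 0`.
#' @param shape shape parameter, `> 0`.
#' @return numeric vector of positive draws.
#' @export
rinvgauss <- function(n, mean = 1, shape = 1) {
  stopifnot(mean > 0, shape > 0)
  nu <- rnorm(n)^2
  w <- mean * nu
  x <- mean * (1 + (w - sqrt(w * (4 * shape + w))) / (2 * shape))
  u <- runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Poisson inverse-Gaussian random draws
#'
#' Sampled as a Poisson mixed over inverse-Gaussian latent rates:
#' `Z ~ IG(1, 1/sigma)`, `Y | Z ~ Poisson(mu * Z)` — the same
#' parameterization as [dpig()].
#'
#' @inheritParams dpig
#' @param n number of draws.
#' @export
rpig <- function(n, mu, sigma) {
  if (sigma < 1e-12) return(rpois(n, mu))
  z <- rinvgauss(n, mean = 1, shape = 1 / sigma)
  rpois(n, mu * z)
}

#' Zero-inflated Poisson probability mass function
#'
#' `P(0) = pi + (1 - pi) * exp(-mu)`; `P(y > 0) = (1 - pi) * Poisson(y; mu)`.
#'
#' @param y vector of non-negative integer counts.
#' @param mu Poisson-component mean, `> 0`.
#' @param pi zero-inflation probability in `[0, 1)`.
#' @param log if `TRUE` return log-probabilities.
#' @export
dzip <- function(y, mu, pi, log = FALSE) {
  if (any(pi < 0 | pi >= 1)) stop("'pi' must be in [0, 1)")
  n <- max(length(y), length(mu), length(pi))
  y <- rep_len(y, n); mu <- rep_len(mu, n); pi <- rep_len(pi, n)
  lp <- log1p(-pi) + dpois(y, mu, log = TRUE)
  zero <- y == 0
  if (any(zero))
    lp[zero] <- log(pi[zero] + exp(log1p(-pi[zero]) - mu[zero]))
  if (log) lp else exp(lp)
}

#' Zero-inflated Poisson cumulative distribution function
#' @inheritParams dzip
#' @param q vector of quantiles.
#' @export
pzip <- function(q, mu, pi) {
  pi + (1 - pi) * ppois(q, mu)
}

#' Zero-inflated Poisson random draws
#' @inheritParams dzip
#' @param n number of draws.
#' @export
rzip <- function(n, mu, pi) {
  ifelse(runif(n) < pi, 0L, rpois(n, mu))
}
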