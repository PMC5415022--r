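# Generalized autoregressive moving average (GARMA) models for the hourly
# minutes-detected series.  The conditional mean follows the link-scale
# recursion
#
#   g(mu_t) = X_t' beta
#           + sum_{j=1}^{p} phi_j   { g(y*_{t-j}) - X_{t-j}' beta }
#           + sum_{j=1}^{q} theta_j { g(y*_{t-j}) - g(mu_{t-j}) }
#
# with natural-log link, y* = max(y, c) to keep g(Y) finite at zero, and a
# clean restart of the recursion after every recording gap.  Conditional
# maximum likelihood with Poisson, Poisson inverse-Gaussian or
# zero-inflated Poisson distributions.

#' Sinusoidal harmonic design matrix for diel and seasonal cycles
#'
#' Builds the regression covariates used by the temporal-occurrence
#' models: an intercept plus one sine/cosine pair per cycle,
#' `sin(2*pi*t/d)` and `cos(2*pi*t/d)`, where for the diel pair `t` is the
#' hour of day (EST) and `d = 24`, and for the seasonal pair `t` is the
#' Julian day and `d` the calendar length of that year (365 or 366).
#'
#' @param timestamps `POSIXct` vector (interpreted in fixed-offset EST).
#' @param terms which cycles to include: any of `"hour"`, `"jday"`.
#' @param year_length `"calendar"` uses each year's true length;
#'   `"fixed365"` uses 365 throughout.
#' @return numeric matrix with an `(Intercept)` column and a
#'   `sin_*`/`cos_*` pair per term.
#' @export
harmonic_design <- function(timestamps, terms = c("hour", "jday"),
                            year_length = c("calendar", "fixed365")) {
  year_length <- match.arg(year_length)
  terms <- match.arg(terms, c("hour", "jday"), several.ok = TRUE)
  n <- length(timestamps)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if ("hour" %in% terms) {
    t_h <- hour_of_day(timestamps)
    X <- cbind(X, sin_hour = sin(2 * pi * t_h / 24),
               cos_hour = cos(2 * pi * t_h / 24))
  }
  if ("jday" %in% terms) {
    t_j <- julian_day(timestamps)
    d <- if (year_length == "calendar") year_length(timestamps) else 365
    X <- cbind(X, sin_jday = sin(2 * pi * t_j / d),
               cos_jday = cos(2 * pi * t_j / d))
  }
  X
}

#' Link-scale GARMA mean recursion
#'
#' Evaluates the conditional means `mu_t` implied by a parameter set,
#' restarting the recursion whenever the segment id changes (lagged terms
#' that would reach across a recording gap contribute zero).
#'
#' @param beta regression coefficients (length `ncol(design)`).
#' @param phi autoregressive parameters (length `p`; may be empty).
#' @param theta moving-average parameters (length `q`; may be empty).
#' @param y observed counts.
#' @param design covariate matrix from [harmonic_design()] (or any
#'   numeric matrix with one row per observation).
#' @param segments integer vector marking contiguous runs of observations;
#'   defaults to a single segment.
#' @param c_offset zero offset `c > 0`: the link is applied to
#'   `max(y, c_offset)`.
#' @return numeric vector of conditional means `mu_t > 0`.
#' @export
garma_mean <- function(beta, phi = numeric(), theta = numeric(), y, design,
                       segments = NULL, c_offset = 0.1) {
  stopifnot(length(y) == nrow(design), c_offset > 0)
  if (is.null(segments)) segments <- rep(1L, length(y))
  if (length(segments) != length(y))
    stop("'segments' must annotate every observation (gap annotation)")
  xb <- drop(design %*% beta)
  gy <- log(pmax(y, c_offset))
  eta <- .garma_eta_cpp(xb, gy, as.integer(segments), as.numeric(phi),
                        as.numeric(theta))
  exp(eta)
}

# negative log-likelihood factory; param layout: beta | phi | theta | extra
garma_nll <- function(y, X, seg, dist, p, q, c_offset) {
  n <- length(y)
  k <- ncol(X)
  gy <- log(pmax(y, c_offset))
  function(par) {
    beta <- par[seq_len(k)]
    phi <- if (p > 0) par[k + seq_len(p)] else numeric()
    theta <- if (q > 0) par[k + p + seq_len(q)] else numeric()
    xb <- drop(X %*% beta)
    eta <- .garma_eta_cpp(xb, gy, seg, phi, theta)
    if (any(!is.finite(eta)) || any(abs(eta) > 30)) return(1e10)
    mu <- exp(eta)
    ll <- switch(dist,
      poisson = sum(dpois(y, mu, log = TRUE)),
      pig = .pig_loglik_cpp(as.integer(y), mu, exp(par[k + p + q + 1])),
      zip = {
        pi0 <- plogis(par[k + p + q + 1])
        sum(dzip(y, mu, pi0, log = TRUE))
      })
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

#' Fit a GARMA model by conditional maximum likelihood
#'
#' Maximizes the conditional likelihood of a GARMA(p, q) model with
#' log link over regression, autoregressive, moving-average and
#' distribution parameters, using BFGS from several seed-controlled
#' starting points (one moment-based start plus jittered restarts; the
#' best optimum is kept).  Standard errors come from the numerical
#' Hessian at the optimum.
#'
#' @inheritParams garma_mean
#' @param dist conditional distribution: `"poisson"`, `"pig"`
#'   (Poisson inverse-Gaussian, dispersion `sigma`, variance
#'   `mu(1+sigma*mu)`), or `"zip"` (zero-inflated Poisson, zero mass `pi`).
#' @param p,q autoregressive and moving-average orders (`>= 0`).
#' @param n_starts number of optimizer starts (first is moment-based,
#'   the rest jittered; uses the current RNG stream).
#' @param compute_residuals if `TRUE` (default) attach randomized quantile
#'   residuals (randomization uses the current RNG stream).
#' @return an object of class `"garma_fit"`: coefficients, `phi`, `theta`,
#'   `sigma`/`pi` as applicable, conditional means, log-likelihood, AIC
#'   (`2k - 2 logLik` with `k` counting every free parameter), standard
#'   errors, convergence flag and quantile residuals.
#' @export
fit_garma <- function(y, design, dist = c("poisson", "pig", "zip"),
                      p = 0, q = 0, segments = NULL, c_offset = 0.1,
                      n_starts = 5, compute_residuals = TRUE) {
  dist <- match.arg(dist)
  y <- as.numeric(y)
  X <- as.matrix(design)
  stopifnot(length(y) == nrow(X), p >= 0, q >= 0, c_offset > 0)
  if (length(y) < 50)
    stop("need at least 50 complete observations to fit a GARMA model")
  if (all(y == y[1]))
    stop("response series is constant (all values ", y[1],
         "); the model is not identifiable")
  if (is.null(segments)) segments <- rep(1L, length(y))
  seg <- as.integer(segments)
  k <- ncol(X)
  npar <- k + p + q + as.integer(dist %in% c("pig", "zip"))
  nll <- garma_nll(y, X, seg, dist, p, q, c_offset)

  ybar <- mean(y)
  start0 <- numeric(npar)
  start0[1] <- log(max(ybar, c_offset))
  if (dist == "pig") {
    sig0 <- max((stats::var(y) / ybar - 1) / max(ybar, 0.1), 0.05)
    start0[npar] <- log(sig0)
  }
  if (dist == "zip") start0[npar] <- qlogis(0.2)

  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- if (s == 1) start0 else start0 + rnorm(npar, 0, 0.25)
    opt <- tryCatch(
      optim(st, nll, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("GARMA optimization failed from every start")

  par <- best$par
  hess <- tryCatch(optimHess(par, nll), error = function(e) NULL)
  vcov <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) NULL) else NULL
  se <- if (!is.null(vcov)) sqrt(pmax(diag(vcov), 0)) else rep(NA_real_, npar)

  # numerical gradient norm at the optimum for the convergence report
  eps <- 1e-5
  gr <- vapply(seq_len(npar), function(i) {
    d <- numeric(npar); d[i] <- eps
    (nll(par + d) - nll(par - d)) / (2 * eps)
  }, numeric(1))
  grad_norm <- sqrt(sum(gr^2))
  converged <- best$convergence == 0 && is.finite(grad_norm) &&
    grad_norm < 1e-3 * (1 + abs(best$value))

  beta <- setNames(par[seq_len(k)], colnames(X))
  phi <- if (p > 0) par[k + seq_len(p)] else numeric()
  theta <- if (q > 0) par[k + p + seq_len(q)] else numeric()
  sigma <- if (dist == "pig") exp(par[npar]) else NULL
  pi0 <- if (dist == "zip") plogis(par[npar]) else NULL
  mu <- garma_mean(beta, phi, theta, y, X, seg, c_offset)
  loglik <- -best$value
  par_names <- c(colnames(X),
                 if (p > 0) paste0("phi", seq_len(p)),
                 if (q > 0) paste0("theta", seq_len(q)),
                 if (dist == "pig") "log_sigma",
                 if (dist == "zip") "logit_pi")

  fit <- structure(list(
    coefficients = beta, phi = phi, theta = theta,
    sigma = sigma, pi = pi0,
    dist = dist, p = p, q = q, c_offset = c_offset,
    mu = mu, loglik = loglik, n = length(y), n_par = npar,
    aic = 2 * npar - 2 * loglik,
    par = setNames(par, par_names), se = setNames(se, par_names),
    vcov = vcov, converged = converged, grad_norm = grad_norm,
    y = y, design = X, segments = seg
  ), class = "garma_fit")
  if (compute_residuals)
    fit$residuals <- quantile_residuals(fit)
  fit
}

#' @export
print.garma_fit <- function(x, ...) {
  cat(sprintf("GARMA(%d,%d) fit, %s distribution, n = %d\n",
              x$p, x$q, x$dist, x$n))
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  if (length(x$phi)) cat("phi:  ", round(x$phi, 4), "\n")
  if (length(x$theta)) cat("theta:", round(x$theta, 4), "\n")
  if (!is.null(x$sigma)) cat("sigma:", round(x$sigma, 4), "\n")
  if (!is.null(x$pi)) cat("pi:   ", round(x$pi, 4), "\n")
  cat(sprintf("logLik = %.2f, AIC = %.2f, converged = %s\n",
              x$loglik, x$aic, x$converged))
  invisible(x)
}

#' @export
logLik.garma_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, class = "logLik")
}

#' @export
AIC.garma_fit <- function(object, ..., k = 2) {
  k * object$n_par - 2 * object$loglik
}

# randomized quantile residuals for a discrete-response fit: uniform draw
# between F(y-1) and F(y), mapped through the standard-normal quantile
quantile_residuals <- function(fit) {
  y <- fit$y; mu <- fit$mu; n <- length(y)
  cdf <- function(q) {
    out <- numeric(n)
    neg <- q < 0
    switch(fit$dist,
      poisson = { out <- ppois(q, mu) },
      pig = {
        # accumulate the pmf up to each observation's own count
        acc <- numeric(n)
        for (j in 0:max(0, max(q))) {
          take <- q >= j
          if (!any(take)) break
          acc[take] <- acc[take] + dpig(j, mu[take], fit$sigma)
        }
        out <- pmin(acc, 1)
      },
      zip = { out <- pzip(q, mu, fit$pi) })
    out[neg] <- 0
    out
  }
  f_hi <- cdf(y)
  f_lo <- cdf(y - 1)
  u <- runif(length(y), f_lo, f_hi)
  qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

#' Select the minimum-AIC fit
#'
#' @param fits list of `garma_fit` (or any objects with `aic` and `n_par`
#'   elements) fitted to the same observations.
#' @return the fit with the lowest AIC; ties broken toward fewer
#'   parameters.
#' @export
aic_select <- function(fits) {
  if (length(fits) == 0) stop("no fits supplied")
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  npar <- vapply(fits, function(f) f$n_par, numeric(1))
  fits[[order(aics, npar)[1]]]
}

#' Residual autocorrelation diagnostics
#'
#' Sample ACF and PACF of a fit's quantile residuals with the usual
#' white-noise reference band `+/- 1.96 / sqrt(n)`.
#'
#' @param fit a `garma_fit`, or any numeric residual vector.
#' @param max_lag largest lag examined.
#' @return list with `acf` and `pacf` value vectors (lags `1..max_lag`),
#'   the `band` half-width, counts outside the band, and a `degenerate`
#'   flag set for constant input (for which autocorrelation is undefined).
#' @export
residual_diagnostics <- function(fit, max_lag = 40) {
  r <- if (inherits(fit, "garma_fit")) fit$residuals else as.numeric(fit)
  if (is.null(r)) stop("fit carries no residuals")
  n <- length(r)
  if (sd(r) == 0 || !is.finite(sd(r))) {
    return(list(acf = rep(NA_real_, max_lag), pacf = rep(NA_real_, max_lag),
                band = 1.96 / sqrt(n), n_outside_acf = NA_integer_,
                n_outside_pacf = NA_integer_, degenerate = TRUE))
  }
  a <- acf(r, lag.max = max_lag, plot = FALSE)$acf[-1]
  p <- pacf(r, lag.max = max_lag, plot = FALSE)$acf[, , 1]
  band <- 1.96 / sqrt(n)
  list(acf = as.numeric(a), pacf = as.numeric(p), band = band,
       n_outside_acf = sum(abs(a) > band),
       n_outside_pacf = sum(abs(p) > band),
       degenerate = FALSE)
}
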