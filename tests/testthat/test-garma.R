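# GARMA engine: harmonic design, mean recursion, likelihood fitting,
# AIC selection, residual diagnostics.

test_that("harmonic design hits the unit circle at the standard angles", {
  ts <- as.POSIXct(c("2015-06-01 00:00", "2015-06-01 06:00"), tz = est_tz())
  X <- harmonic_design(ts)
  expect_equal(unname(X[1, c("sin_hour", "cos_hour")]), c(0, 1),
               tolerance = 1e-12)
  expect_equal(unname(X[2, c("sin_hour", "cos_hour")]), c(1, 0),
               tolerance = 1e-12)
  # day 365 of a 365-day year wraps onto the start of the cycle
  t3 <- as.POSIXct("2015-12-31 00:00", tz = est_tz())
  X3 <- harmonic_design(t3)
  expect_equal(unname(X3[1, "cos_jday"]), cos(2 * pi * 365 / 365),
               tolerance = 1e-12)
  expect_lt(abs(X3[1, "sin_jday"] - 0), 1e-12)
  # pythagorean identity for every pair
  set.seed(1)
  tt <- as.POSIXct("2015-01-01", tz = est_tz()) + runif(50, 0, 3e7)
  Xr <- harmonic_design(tt)
  expect_lt(max(abs(Xr[, "sin_hour"]^2 + Xr[, "cos_hour"]^2 - 1)), 1e-12)
  expect_lt(max(abs(Xr[, "sin_jday"]^2 + Xr[, "cos_jday"]^2 - 1)), 1e-12)
})

test_that("mean recursion reduces to the GLM mean with empty or zero
           AR/MA terms", {
  set.seed(2)
  n <- 200
  X <- cbind(1, rnorm(n))
  beta <- c(0.5, 0.3)
  y <- rpois(n, exp(drop(X %*% beta)))
  mu_glm <- exp(drop(X %*% beta))
  expect_equal(garma_mean(beta, y = y, design = X), mu_glm,
               tolerance = 1e-12)
  expect_equal(garma_mean(beta, phi = 0, theta = 0, y = y, design = X),
               mu_glm, tolerance = 1e-12)
})

test_that("mean recursion equals a hand-unrolled five-step computation", {
  y <- c(2, 0, 5, 1, 3)
  X <- matrix(1, 5, 1)
  beta <- 0.7; phi <- 0.4; theta <- 0.3; cc <- 0.1
  gy <- log(pmax(y, cc))
  # unrolled by hand, spreadsheet style
  eta <- numeric(5)
  eta[1] <- 0.7
  eta[2] <- 0.7 + phi * (gy[1] - 0.7) + theta * (gy[1] - eta[1])
  eta[3] <- 0.7 + phi * (gy[2] - 0.7) + theta * (gy[2] - eta[2])
  eta[4] <- 0.7 + phi * (gy[3] - 0.7) + theta * (gy[3] - eta[3])
  eta[5] <- 0.7 + phi * (gy[4] - 0.7) + theta * (gy[4] - eta[4])
  expect_equal(garma_mean(beta, phi, theta, y, X, c_offset = cc),
               exp(eta), tolerance = 1e-12)
})

test_that("recursion restarts cleanly at segment boundaries", {
  y <- c(4, 4, 4, 4)
  X <- matrix(1, 4, 1)
  mu <- garma_mean(0.2, phi = 0.5, y = y, design = X,
                   segments = c(1, 1, 2, 2))
  # observation 3 opens a new segment: no lagged term
  expect_equal(mu[3], exp(0.2), tolerance = 1e-12)
  expect_equal(mu[1], exp(0.2), tolerance = 1e-12)
  expect_gt(mu[2], exp(0.2))  # positive feedback from y=4 above mean
  expect_equal(mu[4], mu[2], tolerance = 1e-12)
})

test_that("GLM limit of the GARMA fit matches an independent IRLS
           implementation to 1e-4", {
  set.seed(3)
  n <- 2000
  ts <- seq(as.POSIXct("2015-01-01", tz = est_tz()), by = "hour",
            length.out = n)
  X <- harmonic_design(ts)
  beta <- c(0.8, 0.3, -0.2, 0.4, 0.5)
  y <- rpois(n, exp(drop(X %*% beta)))
  fit <- fit_garma(y, X, "poisson", p = 0, q = 0, n_starts = 1)
  oracle <- glm(y ~ X - 1, family = poisson())
  expect_lt(max(abs(unname(fit$coefficients) - unname(coef(oracle)))), 1e-4)
  expect_lt(abs(fit$loglik - as.numeric(logLik(oracle))), 1e-3)
})

test_that("optimization never ends above its moment-based start", {
  set.seed(4)
  n <- 500
  X <- matrix(1, n, 1)
  y <- rpois(n, 2)
  nll <- porpoisepam:::garma_nll(y, X, rep(1L, n), "poisson", 1, 0, 0.1)
  start_val <- nll(c(log(mean(y)), 0))
  fit <- fit_garma(y, X, "poisson", p = 1, q = 0, n_starts = 2)
  expect_lte(-fit$loglik, start_val + 1e-8)
})

test_that("degenerate inputs are refused informatively", {
  X <- matrix(1, 100, 1)
  expect_error(fit_garma(rep(0, 100), X, "poisson"), "constant")
  expect_error(fit_garma(rpois(40, 2), matrix(1, 40, 1), "poisson"),
               "at least 50")
})

test_that("AIC selection returns the minimum and breaks ties toward
           fewer parameters", {
  f1 <- list(aic = 100, n_par = 5)
  f2 <- list(aic = 98, n_par = 7)
  f3 <- list(aic = 98, n_par = 6)
  expect_identical(aic_select(list(f1)), f1)
  expect_identical(aic_select(list(f1, f2, f3)), f3)
  expect_error(aic_select(list()), "no fits")
})

test_that("fit is invariant to shifting the diel covariate by a full
           period", {
  ts <- seq(as.POSIXct("2015-03-01", tz = est_tz()), by = "hour",
            length.out = 240)
  X1 <- harmonic_design(ts, terms = "hour")
  X2 <- harmonic_design(ts + 24 * 3600, terms = "hour")
  expect_equal(X1, X2, tolerance = 1e-12)
})

test_that("residual diagnostics behave for white noise, AR(1) input and
           constant input", {
  set.seed(5)
  wn <- rnorm(3000)
  d <- residual_diagnostics(wn, max_lag = 40)
  expect_lte(d$n_outside_acf, 5)   # ~2 expected at the 95% band
  expect_false(d$degenerate)

  phi <- 0.6
  ar <- as.numeric(arima.sim(list(ar = phi), 5000))
  da <- residual_diagnostics(ar, max_lag = 10)
  expect_lt(abs(da$acf[1] - phi), 0.05)

  dc <- residual_diagnostics(rep(1, 100))
  expect_true(dc$degenerate)
  expect_true(all(is.na(dc$acf)))
})

test_that("quantile residuals of a well-specified fit are near standard
           normal and serially unstructured", {
  set.seed(6)
  n <- 3000
  ts <- seq(as.POSIXct("2015-01-01", tz = est_tz()), by = "hour",
            length.out = n)
  X <- harmonic_design(ts)
  beta <- c(1, 0.3, 0.4, 0.2, 0.3)
  y <- rpois(n, exp(drop(X %*% beta)))
  fit <- fit_garma(y, X, "poisson", n_starts = 1)
  r <- fit$residuals
  expect_lt(abs(mean(r)), 0.08)
  expect_lt(abs(sd(r) - 1), 0.08)
  d <- residual_diagnostics(fit)
  expect_lte(d$n_outside_acf / 40, 0.15)
})
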