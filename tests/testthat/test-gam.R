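# Cyclic-spline GAM engine, confusion matrices and ROC AUC.

test_that("cyclic basis satisfies the periodicity and smoothness
           contracts", {
  k <- 10; period <- 24
  set.seed(1)
  b <- rnorm(k - 1)
  f <- function(x) drop(cyclic_basis(x, period, k) %*% b)
  expect_lt(abs(f(0) - f(period)), 1e-10)
  eps <- 1e-5
  d0 <- (f(eps) - f(0)) / eps
  dP <- (f(period) - f(period - eps)) / eps
  expect_lt(abs(d0 - dP), 1e-3)
  expect_error(cyclic_basis(1:5, 24, k = 3), "at least 4")
})

test_that("an unpenalized cyclic fit interpolates a pure sinusoid to
           1e-3", {
  x <- seq(0, 24, length.out = 481)[-481]
  y <- sin(2 * pi * x / 24)
  X <- cyclic_basis(x, 24, k = 10)
  b <- qr.solve(X, y)
  grid <- seq(0, 24, length.out = 300)
  err <- drop(cyclic_basis(grid, 24, 10) %*% b) - sin(2 * pi * grid / 24)
  expect_lt(max(abs(err)), 1e-3)
})

test_that("a Gaussian fit with one linear term matches ordinary least
           squares to 1e-8", {
  set.seed(2)
  d <- data.frame(x = runif(100), y = rnorm(100))
  fit <- fit_gam(d, "y", list(lin("x")), family = "gaussian")
  ols <- lm(y ~ x, data = d)
  expect_lt(max(abs(fit$coefficients - unname(coef(ols)))), 1e-8)
})

test_that("a nearly unpenalized smooth with k close to n reproduces the
           data", {
  set.seed(3)
  x <- seq(0, 10, length.out = 30)   # data at the (evenly spaced) knots
  y <- rnorm(30)
  d <- data.frame(x = x, y = y)
  fit <- fit_gam(d, "y", list(s_spline("x", k = 30)),
                 family = "gaussian", lambda_grid = 1e-10)
  expect_lt(max(abs(fit$fitted - y)), 1e-3)
})

test_that("an infinitely penalized cyclic term shrinks to a constant
           with EDF near zero", {
  set.seed(4)
  d <- data.frame(x = runif(300, 0, 24))
  d$y <- sin(2 * pi * d$x / 24) + rnorm(300, 0, 0.2)
  fit <- fit_gam(d, "y", list(s_cyclic("x", 24)), family = "gaussian",
                 lambda_grid = 1e12)
  expect_lt(fit$edf[["x"]], 1e-4)
  rc <- response_curve(fit, "x")
  expect_lt(max(abs(rc$fit)), 1e-4)
})

test_that("smooth recovery: Gaussian cyclic fit tracks a known cyclic
           function within the expected noise envelope", {
  set.seed(5)
  n <- 500; k <- 10; sigma <- 0.1
  x <- runif(n, 0, 24)
  f <- function(x) 0.7 * sin(2 * pi * x / 24) + 0.3 * cos(4 * pi * x / 24)
  d <- data.frame(x = x, y = f(x) + rnorm(n, 0, sigma))
  fit <- fit_gam(d, "y", list(s_cyclic("x", 24, k)), family = "gaussian")
  grid <- seq(0, 24, length.out = 200)
  rmse <- sqrt(mean((predict(fit, data.frame(x = grid)) - f(grid))^2))
  expect_lt(rmse, 2 * sigma / sqrt(n / k) * 3)
})

test_that("fit agrees with an established penalized-spline oracle on a
           shared basis", {
  library(mgcv)
  set.seed(6)
  n <- 400
  x <- runif(n, 0, 24)
  d <- data.frame(x = x, y = sin(2 * pi * x / 24) + rnorm(n, 0, 0.3))
  ours <- fit_gam(d, "y", list(s_cyclic("x", 24, k = 10)),
                  family = "gaussian")
  oracle <- gam(y ~ s(x, bs = "cc", k = 10), data = d,
                knots = list(x = seq(0, 24, length.out = 10)))
  grid <- data.frame(x = seq(0, 24, length.out = 100))
  expect_lt(max(abs(predict(ours, grid) -
                      as.numeric(predict(oracle, grid)))), 0.05)
})

test_that("binomial fits keep probabilities inside (0,1) and the
           penalized deviance decreases monotonically", {
  set.seed(7)
  n <- 600
  h <- runif(n, 0, 24)
  p <- plogis(0.3 + 1.2 * cos(2 * pi * (h - 21) / 24))
  d <- data.frame(hour = h, y = rbinom(n, 1, p))
  fit <- fit_gam(d, "y", list(s_cyclic("hour", 24)), family = "binomial")
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  expect_true(all(diff(fit$pdev_trace) <= 1e-8))
  expect_false(fit$separation)
  expect_true(all(fit$edf >= 0 & fit$edf <= 10 - 1))
  expect_gte(fit$deviance_explained, 0)
  expect_lte(fit$deviance_explained, 1)
})

test_that("confusion matrix matches a hand tally and handles the trivial
           threshold cases", {
  obs <- c(1, 1, 1, 0, 0, 0, 1, 0, 1, 0)
  prob <- c(0.9, 0.8, 0.3, 0.2, 0.6, 0.1, 0.55, 0.45, 0.5, 0.5)
  cm <- confusion_matrix(obs, prob, threshold = 0.5)
  # hand tally at 0.5 (inclusive): predictions 1,1,0,0,1,0,1,0,1,1
  expect_equal(cm$counts["present", "present"], 4)
  expect_equal(cm$counts["present", "absent"], 1)
  expect_equal(cm$counts["absent", "absent"], 3)
  expect_equal(cm$counts["absent", "present"], 2)
  expect_equal(cm$correct_presence, 4 / 5)

  perfect <- confusion_matrix(c(0, 1, 0, 1), c(0, 1, 0, 1), 0.5)
  expect_equal(perfect$counts["present", "absent"], 0)
  expect_equal(perfect$counts["absent", "present"], 0)

  all_absent <- confusion_matrix(c(0, 1, 1), rep(0.4, 3), 0.5)
  expect_equal(sum(all_absent$counts[, "present"]), 0)
  expect_error(confusion_matrix(c(0, 2), c(0.1, 0.2)), "binary")
})

test_that("ROC AUC equals the exhaustive pairwise oracle and is
           transform invariant", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  obs <- c(1, 0, 1, 0, 1, 0)
  sc <- c(0.9, 0.4, 0.4, 0.2, 0.7, 0.7)   # two ties, one across classes
  expect_equal(roc_auc(obs, sc), auc_bruteforce(obs, sc), tolerance = 1e-12)
  set.seed(8)
  o <- rbinom(50, 1, 0.5); s <- rnorm(50)
  expect_equal(roc_auc(o, s), auc_bruteforce(o, s), tolerance = 1e-12)
  expect_equal(roc_auc(o, exp(3 * s) + 5), roc_auc(o, s), tolerance = 1e-12)
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("centered response curves average to zero and widen where the
           data thin out", {
  set.seed(9)
  x <- c(runif(180, 0, 6), runif(20, 6, 10))   # sparse right-hand side
  d <- data.frame(x = x, y = sin(x) + rnorm(200, 0, 0.3))
  fit <- fit_gam(d, "y", list(s_spline("x", k = 10)), family = "gaussian")
  rc <- response_curve(fit, "x")
  expect_lt(abs(mean(rc$fit)), 1e-10)
  expect_true(all(rc$upper >= rc$fit & rc$lower <= rc$fit))
  expect_gt(mean(rc$se[rc$x > 9]), mean(rc$se[rc$x >= 2 & rc$x <= 4]))
  expect_equal(sort(attr(rc, "rug")), sort(x))
  expect_error(response_curve(fit, "zzz"), "not a term")
})
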