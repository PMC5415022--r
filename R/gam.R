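# Penalized regression-spline GAM engine with cyclic and natural cubic
# smooths, binomial (logit) and Gaussian (identity) families.  Smoothing
# parameters are chosen by GCV over a log-spaced grid, coordinate-wise.
# Each smooth carries a sum-to-zero constraint (absorbed by a QR
# reparameterization) so the intercept is identifiable.

#' Smooth- and linear-term constructors for [fit_gam()]
#'
#' `s_cyclic()` declares a cyclic cubic regression spline over a known
#' period (hour of day: 24; Julian day: 366 so leap days are valid and
#' day 366 wraps onto day 1), `s_spline()` a natural cubic regression
#' spline, and `lin()` an unpenalized linear term.
#'
#' @param var covariate name in the model data.
#' @param period cycle length for the cyclic basis.
#' @param k basis dimension (number of knots, `>= 4`).
#' @return a term specification list.
#' @export
s_cyclic <- function(var, period, k = 10) {
  if (k < 4) stop("'k' must be at least 4")
  stopifnot(period > 0)
  list(type = "cyclic", var = var, period = period, k = k)
}

#' @rdname s_cyclic
#' @export
s_spline <- function(var, k = 10) {
  if (k < 4) stop("'k' must be at least 4")
  list(type = "spline", var = var, k = k)
}

#' @rdname s_cyclic
#' @export
lin <- function(var) list(type = "linear", var = var)

# build one term's design block, absorbing the sum-to-zero constraint for
# smooths and normalizing the penalty to unit Frobenius norm
build_term <- function(term, x) {
  if (term$type == "linear") {
    return(list(X = matrix(x, ncol = 1, dimnames = list(NULL, term$var)),
                S = NULL, Z = NULL, info = term))
  }
  raw <- if (term$type == "cyclic") {
    cyclic_basis(x, term$period, term$k)
  } else {
    natural_basis(x, term$k)
  }
  S <- attr(raw, "S")
  info <- c(term, list(knots = attr(raw, "knots"),
                       range = if (term$type == "spline") range(x)))
  Cc <- colSums(raw)
  Z <- qr.Q(qr(matrix(Cc, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
  Xz <- unclass(raw) %*% Z
  Sz <- t(Z) %*% S %*% Z
  Sz <- Sz / norm(Sz, "F")
  list(X = Xz, S = Sz, Z = Z, info = info)
}

# evaluate a stored term block at new covariate values
eval_term <- function(blk, x) {
  info <- blk$info
  if (info$type == "linear")
    return(matrix(x, ncol = 1))
  raw <- if (info$type == "cyclic") {
    cyclic_basis(x, info$period, info$k)
  } else {
    natural_basis(x, info$k, range = info$range)
  }
  unclass(raw) %*% blk$Z
}

family_funs <- function(family) {
  switch(family,
    binomial = list(
      linkinv = plogis,
      mu_eta = function(eta) { p <- plogis(eta); p * (1 - p) },
      dev = function(y, mu) {
        mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
        -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
      },
      init = function(y) (y + 0.5) / 2),
    gaussian = list(
      linkinv = identity,
      mu_eta = function(eta) rep(1, length(eta)),
      dev = function(y, mu) sum((y - mu)^2),
      init = function(y) y))
}

# penalized IRLS with step halving so the penalized deviance is
# monotonically non-increasing
pirls <- function(X, y, family, Spen, maxit = 100, tol = 1e-9) {
  fam <- family_funs(family)
  n <- length(y)
  pdim <- ncol(X)
  pen <- function(b) drop(t(b) %*% Spen %*% b)
  mu <- fam$init(y)
  eta <- if (family == "binomial") qlogis(pmin(pmax(mu, 1e-3), 1 - 1e-3))
         else mu
  beta <- rep(0, pdim)
  pdev <- fam$dev(y, fam$linkinv(eta)) + 0
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    w <- fam$mu_eta(eta)
    w <- pmax(w, 1e-10)
    z <- eta + (y - fam$linkinv(eta)) / w
    XtW <- t(X * w)
    H <- XtW %*% X + Spen
    bnew <- tryCatch(solve(H, XtW %*% z),
                     error = function(e) stop("singular design matrix"))
    # step halving on the penalized deviance
    step <- 1
    repeat {
      btry <- beta + step * (bnew - beta)
      etat <- drop(X %*% btry)
      ptry <- fam$dev(y, fam$linkinv(etat)) + pen(btry)
      if (is.finite(ptry) && (ptry <= pdev + 1e-10 || step < 1e-8)) break
      step <- step / 2
    }
    beta <- btry; eta <- etat
    conv <- abs(pdev - ptry) < tol * (abs(ptry) + 0.1)
    pdev <- ptry
    trace <- c(trace, pdev)
    if (conv && it > 1) break
  }
  mu <- fam$linkinv(eta)
  w <- pmax(fam$mu_eta(eta), 1e-10)
  XtWX <- t(X * w) %*% X
  Hinv <- solve(XtWX + Spen)
  edf_vec <- rowSums(Hinv * t(XtWX))     # diag of Hinv %*% XtWX
  list(beta = drop(beta), mu = mu, eta = eta,
       deviance = fam$dev(y, mu), pdev_trace = trace,
       edf_vec = edf_vec, edf = sum(edf_vec),
       Hinv = Hinv, XtWX = XtWX, w = w, iterations = it)
}

#' Fit a penalized cyclic-spline GAM
#'
#' Penalized IRLS with per-term smoothing parameters chosen by GCV
#' minimization over a 41-point log-spaced grid, coordinate-wise with two
#' sweeps.  Reports per-term effective degrees of freedom (EDF), deviance
#' explained and adjusted R-squared.
#'
#' @param data data frame holding the response and covariates.
#' @param response name of the response column (0/1 for binomial).
#' @param terms list of term specifications from [s_cyclic()],
#'   [s_spline()], [lin()]; may be empty for an intercept-only model.
#' @param family `"binomial"` (logit link) or `"gaussian"` (identity).
#' @param lambda_grid candidate smoothing parameters (applied to
#'   Frobenius-normalized penalties).
#' @param sweeps coordinate-descent sweeps over the terms.
#' @param gcv_gamma effective-degrees-of-freedom inflation factor in the
#'   GCV score `n D / (n - gamma * EDF)^2`; values around 1.4 counteract
#'   the well-known tendency of plain GCV to undersmooth.
#' @return an object of class `"pam_gam"` with elements including
#'   `coefficients`, `lambda`, `edf` (per term), `edf_total`,
#'   `deviance_explained`, `r_squared`, `aic`, `fitted`, `Vp` (Bayesian
#'   coefficient covariance) and a `separation` flag for binomial fits.
#' @export
fit_gam <- function(data, response, terms = list(),
                    family = c("gaussian", "binomial"),
                    lambda_grid = 10^seq(-4, 6, length.out = 41),
                    sweeps = 2, gcv_gamma = 1.4) {
  family <- match.arg(family)
  y <- data[[response]]
  if (is.logical(y)) y <- as.numeric(y)
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial response must be binary 0/1")
  n <- length(y)
  smooth_idx <- which(vapply(terms, function(t) t$type != "linear",
                             logical(1)))
  for (tm in terms)
    if (!tm$var %in% names(data)) stop("covariate '", tm$var, "' not found")
  for (tm in terms[smooth_idx])
    if (n < 10) stop("need at least 10 observations per smooth term")

  blocks <- lapply(terms, function(tm) build_term(tm, data[[tm$var]]))
  X <- cbind("(Intercept)" = rep(1, n))
  col_of <- vector("list", length(terms))
  for (i in seq_along(blocks)) {
    col_of[[i]] <- ncol(X) + seq_len(ncol(blocks[[i]]$X))
    X <- cbind(X, blocks[[i]]$X)
  }
  pdim <- ncol(X)
  pen_full <- function(lams) {
    Spen <- matrix(0, pdim, pdim)
    for (i in seq_along(blocks)) {
      if (is.null(blocks[[i]]$S)) next
      idx <- col_of[[i]]
      Spen[idx, idx] <- Spen[idx, idx] + lams[i] * blocks[[i]]$S
    }
    Spen
  }

  lams <- ifelse(vapply(blocks, function(b) is.null(b$S), logical(1)), 0, 1)
  gcv <- function(fit) n * fit$deviance /
    (max(n - gcv_gamma * fit$edf, 1))^2
  fit <- pirls(X, y, family, pen_full(lams))
  if (length(smooth_idx) > 0) {
    for (sw in seq_len(sweeps)) {
      for (i in smooth_idx) {
        scores <- vapply(lambda_grid, function(lam) {
          lt <- lams; lt[i] <- lam
          gcv(pirls(X, y, family, pen_full(lt)))
        }, numeric(1))
        lams[i] <- lambda_grid[which.min(scores)]
      }
    }
    fit <- pirls(X, y, family, pen_full(lams))
  }

  edf_term <- vapply(seq_along(blocks), function(i)
    sum(fit$edf_vec[col_of[[i]]]), numeric(1))
  null_dev <- {
    f0 <- pirls(cbind(rep(1, n)), y, family, matrix(0, 1, 1))
    f0$deviance
  }
  dev_expl <- if (null_dev > 0) 1 - fit$deviance / null_dev else 0
  edf_total <- fit$edf
  r2 <- if (null_dev > 0)
    1 - (fit$deviance / max(n - edf_total, 1)) / (null_dev / (n - 1)) else 0
  scale <- if (family == "gaussian")
    fit$deviance / max(n - edf_total, 1) else 1
  loglik <- if (family == "gaussian") {
    s2 <- fit$deviance / n
    -n / 2 * (log(2 * pi * s2) + 1)
  } else {
    -fit$deviance / 2
  }
  # model df for AIC: effective df plus one parameter per estimated
  # smoothing parameter (lambdas are fitted quantities, counted like
  # variance components) plus the Gaussian scale
  k_aic <- edf_total + length(smooth_idx) + (family == "gaussian")
  separation <- family == "binomial" &&
    all(abs(fit$mu - y) < 1e-6)
  term_names <- vapply(terms, function(tm) tm$var, character(1))
  structure(list(
    family = family, response = response, terms = terms, blocks = blocks,
    col_of = col_of, coefficients = fit$beta, lambda = setNames(
      lams, if (length(terms)) term_names else character(0)),
    edf = setNames(edf_term, term_names), edf_total = edf_total,
    deviance = fit$deviance, null_deviance = null_dev,
    deviance_explained = dev_expl, r_squared = r2,
    fitted = fit$mu, linear_predictors = fit$eta,
    Vp = fit$Hinv * scale, scale = scale, loglik = loglik,
    aic = -2 * loglik + 2 * k_aic,
    pdev_trace = fit$pdev_trace, y = y, n = n,
    model_data = data[, unique(vapply(terms, function(tm) tm$var,
                                      character(1))), drop = FALSE],
    separation = separation
  ), class = "pam_gam")
}

#' @export
print.pam_gam <- function(x, ...) {
  cat(sprintf("Penalized spline GAM (%s), n = %d\n", x$family, x$n))
  if (length(x$edf)) {
    cat("Smooth/linear terms (EDF):\n")
    for (i in seq_along(x$edf))
      cat(sprintf("  %-12s EDF = %.2f  lambda = %.3g\n",
                  names(x$edf)[i], x$edf[i], x$lambda[i]))
  }
  cat(sprintf("Deviance explained = %.2f%%, adj. R^2 = %.2f, AIC = %.2f\n",
              100 * x$deviance_explained, x$r_squared, x$aic))
  if (x$separation) cat("WARNING: complete separation detected\n")
  invisible(x)
}

#' @export
predict.pam_gam <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(if (type == "response") object$fitted
           else object$linear_predictors)
  }
  n <- nrow(newdata)
  X <- cbind(rep(1, n))
  for (i in seq_along(object$blocks))
    X <- cbind(X, eval_term(object$blocks[[i]],
                            newdata[[object$terms[[i]]$var]]))
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else family_funs(object$family)$linkinv(eta)
}

#' @export
AIC.pam_gam <- function(object, ..., k = 2) object$aic

#' Centered partial-effect curve of one smooth term
#'
#' Extracts the fitted smooth for one covariate on a grid, centered to
#' mean zero over the grid, with approximate +/- 2 standard-error bands
#' from the Bayesian coefficient covariance.  The covariate's data values
#' are attached as a rug.
#'
#' @param fit a `pam_gam`.
#' @param covariate covariate name of a smooth term in the fit.
#' @param grid evaluation points (default: 200 points across the
#'   covariate's range or period).
#' @return data frame with `x`, `fit`, `se`, `lower`, `upper`; the data
#'   values are attached as attribute `"rug"`.
#' @export
response_curve <- function(fit, covariate, grid = NULL) {
  i <- match(covariate, vapply(fit$terms, function(t) t$var, character(1)))
  if (is.na(i)) stop("covariate '", covariate, "' is not a term in the fit")
  blk <- fit$blocks[[i]]
  info <- blk$info
  if (is.null(grid)) {
    grid <- if (info$type == "cyclic")
      seq(0, info$period, length.out = 200)
    else seq(info$range[1], info$range[2], length.out = 200)
  }
  Xg <- eval_term(blk, grid)
  Xc <- sweep(Xg, 2, colMeans(Xg))
  idx <- fit$col_of[[i]]
  beta <- fit$coefficients[idx]
  v <- drop(Xc %*% beta)
  Vsub <- fit$Vp[idx, idx, drop = FALSE]
  se <- sqrt(pmax(rowSums((Xc %*% Vsub) * Xc), 0))
  out <- data.frame(x = grid, fit = v, se = se,
                    lower = v - 2 * se, upper = v + 2 * se)
  attr(out, "rug") <- fit$model_data[[covariate]]
  out
}

#' Confusion matrix for binary predictions
#'
#' Compares thresholded predicted probabilities to observed
#' presence/absence.
#'
#' @param observed binary 0/1 (or logical) observations.
#' @param predicted_prob predicted probabilities.
#' @param threshold classification threshold (default 0.5).
#' @return list with the 2x2 `counts` matrix (rows: observed, columns:
#'   predicted), `correct_presence` = TP/(TP+FN), `correct_absence` =
#'   TN/(TN+FP), and overall `accuracy`.
#' @export
confusion_matrix <- function(observed, predicted_prob, threshold = 0.5) {
  observed <- as.numeric(observed)
  if (!all(observed %in% c(0, 1))) stop("'observed' must be binary")
  if (length(observed) != length(predicted_prob))
    stop("lengths differ")
  pred <- as.numeric(predicted_prob >= threshold)
  tp <- sum(observed == 1 & pred == 1)
  fn <- sum(observed == 1 & pred == 0)
  tn <- sum(observed == 0 & pred == 0)
  fp <- sum(observed == 0 & pred == 1)
  counts <- matrix(c(tn, fn, fp, tp), 2, 2,
                   dimnames = list(observed = c("absent", "present"),
                                   predicted = c("absent", "present")))
  list(counts = counts,
       correct_presence = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       correct_absence = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(observed))
}

#' Area under the ROC curve
#'
#' Rank-statistic computation: `AUC = P(score+ > score-) + P(tie)/2`,
#' using midranks, so it is invariant under strictly increasing
#' transforms of the scores.
#'
#' @param observed binary 0/1 (or logical) class labels; both classes
#'   must be present.
#' @param scores classifier scores (higher = more likely positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(observed, scores) {
  observed <- as.numeric(observed)
  if (!all(observed %in% c(0, 1))) stop("'observed' must be binary")
  n1 <- sum(observed == 1)
  n0 <- sum(observed == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[observed == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
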