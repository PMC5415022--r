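# Validation of habitat-based monthly density predictions against the
# monthly acoustic detection metrics, by Spearman rank correlation with
# midranks, exact permutation p-values for small n and the
# t-approximation otherwise.

# all permutations of 1..n (n <= 8 in practice: 40,320 rows max)
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rest <- (1:n)[-i]
    out[r + seq_len(nrow(sub)), ] <- cbind(i, matrix(rest[sub], nrow(sub)))
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact small-sample permutation p-value
#'
#' `rho` is the Pearson correlation of midranks (the standard
#' tie-corrected Spearman coefficient).  The two-sided p-value is exact
#' (enumeration of all `n!` permutations of one margin) for `n <= exact_max`
#' and otherwise uses the t-approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @param exact_max largest `n` for which the permutation null is
#'   enumerated exactly (default 8).
#' @return list with `rho`, `p_value`, `n`, `method`, and `degenerate`
#'   (`TRUE`, with `rho = NA`, when either input is constant).
#' @export
spearman <- function(x, y, exact_max = 8) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "degenerate", degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (n <= exact_max) {
    perms <- permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- as.vector((perms_apply(perms, ryc) %*% rxc) / denom)
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method,
       degenerate = FALSE)
}

# permute a centered rank vector by every row of a permutation matrix
perms_apply <- function(perms, v) {
  matrix(v[perms], nrow(perms), ncol(perms))
}

#' Correlate monthly acoustic metrics with density predictions
#'
#' For each site, Spearman-correlates the four monthly acoustic metrics
#' (median PPH per day, total PPH, maximum PPH per day, proportion of
#' days present) with the monthly habitat-based density predictions.
#' Months without acoustic data are dropped pairwise, consistently across
#' the four metrics; a metric that is constant across the aligned months
#' is reported as degenerate (`rho = NA`).  No multiple-testing
#' correction is applied (the tests are reported raw, as flagged in the
#' `multiple_testing` attribute).
#'
#' @param metrics monthly metrics from [monthly_metrics()] (pooled
#'   calendar months).
#' @param predictions density data frame (`site`, `month`,
#'   `density_per_100km2`).
#' @return data frame with one row per site and metric: `site`, `metric`,
#'   `rho`, `p_value`, `n_months`, `degenerate`.
#' @export
validate_density <- function(metrics, predictions) {
  metric_cols <- c(median_pph = "median_pph_per_day",
                   total_pph = "total_pph",
                   max_pph = "max_pph_per_day",
                   proportion_days = "proportion_days_present")
  rows <- list()
  for (site in unique(metrics$site)) {
    m <- metrics[metrics$site == site, , drop = FALSE]
    p <- predictions[predictions$site == site, , drop = FALSE]
    joined <- merge(m, p, by = "month")
    joined <- joined[is.finite(joined$density_per_100km2), , drop = FALSE]
    for (j in seq_along(metric_cols)) {
      nm <- names(metric_cols)[j]
      if (nrow(joined) < 3) {
        rows[[length(rows) + 1]] <- data.frame(
          site = site, metric = nm, rho = NA_real_, p_value = NA_real_,
          n_months = nrow(joined), degenerate = TRUE)
        next
      }
      sp <- spearman(joined[[metric_cols[j]]], joined$density_per_100km2)
      rows[[length(rows) + 1]] <- data.frame(
        site = site, metric = nm, rho = sp$rho, p_value = sp$p_value,
        n_months = sp$n, degenerate = sp$degenerate)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "multiple_testing") <- "none (raw p-values)"
  res
}
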