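# Foraging classification from inter-click intervals and the binomial
# cyclic-GAM model of foraging presence/absence.  A buzz threshold of
# 10 ms (10,000 microseconds), applied inclusively to the minimum ICI of
# all trains pooled within an hour, separates foraging-positive from
# foraging-negative hours.

BUZZ_THRESHOLD_US <- 10000

#' Subset to porpoise-positive detection hours
#'
#' @param hours complete detection-hour data frame.
#' @return the rows with `minutes_detected >= 1`.
#' @export
subset_detection_hours <- function(hours) {
  out <- hours[hours$minutes_detected >= 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify foraging-positive hours from inter-click intervals
#'
#' Pools the ICIs of all (quality-filtered) trains within each
#' porpoise-positive hour and compares the minimum to the buzz threshold,
#' inclusively: an hour with any ICI of 10 ms or less is foraging
#' positive.  The number of ICIs at or below the threshold is recorded as
#' buzz support.
#'
#' @param trains filtered click-train data frame.
#' @param hours complete detection-hour data frame (will be subset to
#'   porpoise-positive hours); every such hour must contain at least one
#'   train.
#' @param threshold_us buzz threshold in microseconds (default 10,000).
#' @return data frame of foraging hours: `site`, `hour_start`,
#'   `minutes_detected`, `min_ici_us`, `n_buzz_icis`, `foraging`.
#' @export
classify_foraging <- function(trains, hours, threshold_us = BUZZ_THRESHOLD_US) {
  hp <- subset_detection_hours(hours)
  if (nrow(hp) == 0) return(
    data.frame(site = character(), hour_start = as.POSIXct(character()),
               minutes_detected = integer(), min_ici_us = numeric(),
               n_buzz_icis = integer(), foraging = logical()))
  th <- floor(as.numeric(trains$start) / 3600) * 3600
  tr_key <- paste(trains$site, th)
  hp_key <- paste(hp$site, as.numeric(hp$hour_start))
  idx <- split(seq_len(nrow(trains)), tr_key)
  min_ici <- numeric(nrow(hp))
  n_buzz <- integer(nrow(hp))
  for (i in seq_len(nrow(hp))) {
    rows <- idx[[hp_key[i]]]
    if (is.null(rows))
      stop("porpoise-positive hour without any train at ", hp$site[i],
           " ", format(hp$hour_start[i]), " (inconsistent inputs)")
    icis <- unlist(trains$icis[rows])
    min_ici[i] <- min(icis)
    n_buzz[i] <- sum(icis <= threshold_us)
  }
  out <- data.frame(site = hp$site, hour_start = hp$hour_start,
                    minutes_detected = hp$minutes_detected,
                    min_ici_us = min_ici, n_buzz_icis = n_buzz,
                    foraging = min_ici <= threshold_us)
  rownames(out) <- NULL
  out
}

#' Buzz-support summary of foraging hours
#'
#' The per-site proportion of foraging-positive hours containing at least
#' `min_buzzes` ICIs at or below the buzz threshold — a robustness check
#' that classification does not hinge on single stray intervals.
#'
#' @param foraging_hours output of [classify_foraging()].
#' @param min_buzzes minimum buzz-ICI count (default 5).
#' @return data frame with `site`, `n_foraging_hours`,
#'   `prop_with_buzz_support`.
#' @export
buzz_support_summary <- function(foraging_hours, min_buzzes = 5) {
  fh <- foraging_hours[foraging_hours$foraging, , drop = FALSE]
  sp <- split(fh, fh$site, drop = TRUE)
  rows <- lapply(sp, function(d)
    data.frame(site = d$site[1], n_foraging_hours = nrow(d),
               prop_with_buzz_support = mean(d$n_buzz_icis >= min_buzzes)))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Binomial cyclic-GAM of foraging presence against hour and Julian day
#'
#' Fits candidate binomial (logit) GAMs of the foraging-positive flag —
#' intercept-only, hour of day, Julian day, and hour + Julian day, each
#' cyclic with period 24 or 366 — and selects by AIC.  The selected fit
#' carries its confusion matrix and ROC AUC.
#'
#' @param foraging_hours output of [classify_foraging()] for one site.
#' @param k basis dimension per smooth.
#' @param min_hours minimum number of porpoise-positive hours required to
#'   fit (sites with fewer are refused, mirroring the exclusion of
#'   sparsely detected sites).
#' @param threshold confusion-matrix probability threshold.
#' @return the selected `pam_gam`, with extra elements `candidates`
#'   (AIC table), `confusion` and `auc`.
#' @export
foraging_gam <- function(foraging_hours, k = 10, min_hours = 24,
                         threshold = 0.5) {
  if (nrow(foraging_hours) < min_hours)
    stop("only ", nrow(foraging_hours), " porpoise-positive hours; ",
         "at least ", min_hours, " required to model foraging")
  y <- as.numeric(foraging_hours$foraging)
  if (length(unique(y)) < 2)
    stop("foraging flag is single-class; GAM not fittable")
  d <- data.frame(
    foraging = y,
    hour = hour_of_day(foraging_hours$hour_start),
    jday = julian_day(foraging_hours$hour_start))
  cand <- list(
    intercept = list(),
    hour = list(s_cyclic("hour", 24, k)),
    jday = list(s_cyclic("jday", 366, k)),
    hour_jday = list(s_cyclic("hour", 24, k), s_cyclic("jday", 366, k)))
  fits <- lapply(cand, function(tm)
    fit_gam(d, "foraging", tm, family = "binomial"))
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  edfs <- vapply(fits, function(f) f$edf_total, numeric(1))
  best <- fits[[order(aics, edfs)[1]]]
  best$candidates <- data.frame(model = names(cand), aic = aics,
                                edf = edfs, row.names = NULL)
  best$confusion <- confusion_matrix(y, best$fitted, threshold)
  best$auc <- roc_auc(y, best$fitted)
  best
}

#' Monthly and diel foraging-proportion tables
#'
#' The proportion of porpoise-positive hours classified foraging-positive
#' per site and calendar month, and per site and hour of day.
#'
#' @param foraging_hours output of [classify_foraging()].
#' @return list with `monthly` and `diel` data frames.
#' @export
foraging_proportions <- function(foraging_hours) {
  fh <- foraging_hours
  fh$month <- as.integer(format(fh$hour_start, "%m", tz = EST_TZ))
  fh$hour <- hour_of_day(fh$hour_start)
  agg <- function(key) {
    sp <- split(fh, fh[c("site", key)], drop = TRUE)
    rows <- lapply(sp, function(dd) {
      r <- data.frame(site = dd$site[1], key = dd[[key]][1],
                      proportion_foraging = mean(dd$foraging),
                      n_hours = nrow(dd))
      names(r)[2] <- key
      r
    })
    res <- do.call(rbind, rows)
    res <- res[order(res$site, res[[key]]), , drop = FALSE]
    rownames(res) <- NULL
    res
  }
  list(monthly = agg("month"), diel = agg("hour"))
}
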