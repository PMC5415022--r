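# Detection processing: click-train quality filtering, minute-level
# binning against recording effort, porpoise-positive hours, monthly
# detection metrics and ISO-week occurrence proportions.
#
# Conventions: all intervals are half-open ([h:00, h+1:00) for hours,
# likewise minutes), so a train ending exactly on a boundary does not
# occupy the next unit.  A train's span is its start time plus the sum of
# its inter-click intervals.  Only hours with a complete 60 minutes of
# recording enter any model.

#' Filter click trains by quality class
#'
#' Keeps only trains whose classifier quality class is in `keep_classes`
#' (the conservative default retains the high- and medium-confidence
#' classes).  Records with an unknown quality label are rejected with a
#' warning; their count is attached as attribute `n_unknown_quality`.
#'
#' @param trains click-train data frame (`site`, `start`, `icis`,
#'   `quality`).
#' @param keep_classes character vector of quality classes to retain.
#' @return the filtered subsequence, input order preserved.
#' @export
filter_trains <- function(trains, keep_classes = c("Hi", "Med")) {
  valid <- c("Hi", "Med", "Low")
  unknown <- !(trains$quality %in% valid)
  if (any(unknown))
    warning(sum(unknown), " train(s) with unknown quality class rejected")
  out <- trains[!unknown & trains$quality %in% keep_classes, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unknown_quality") <- sum(unknown)
  out
}

# duration of each train in seconds (sum of its ICIs, microseconds)
train_span_s <- function(trains) {
  vapply(trains$icis, function(ic) sum(ic) / 1e6, numeric(1))
}

#' Bin click trains into hourly detection-positive minutes
#'
#' Produces one row per recorded hour per site (every hour intersecting a
#' recording-effort interval), with the number of minutes in that hour
#' during which at least one train was present.  A minute is
#' detection-positive iff any train overlaps any part of it; overlapping
#' trains within a minute count once.  An hour is `complete` when it lies
#' entirely inside one effort interval; incomplete hours are retained with
#' `complete = FALSE` so callers can exclude them from modelling.
#'
#' @param trains filtered click-train data frame.
#' @param effort effort data frame (`site`, `start`, `end`), non-overlapping
#'   intervals per site.
#' @return data frame of detection hours: `site`, `hour_start` (`POSIXct`,
#'   EST), `minutes_detected` (0--60), `complete`.
#' @export
bin_hourly <- function(trains, effort) {
  stopifnot(all(c("site", "start", "end") %in% names(effort)))
  out <- list()
  for (site in unique(effort$site)) {
    es <- effort[effort$site == site, , drop = FALSE]
    es <- es[order(es$start), , drop = FALSE]
    e0 <- as.numeric(es$start); e1 <- as.numeric(es$end)
    hours <- do.call(c, lapply(seq_len(nrow(es)), function(i)
      seq(floor(e0[i] / 3600) * 3600, ceiling(e1[i] / 3600) * 3600 - 3600,
          by = 3600)))
    hours <- unique(hours)
    complete <- vapply(hours, function(h)
      any(h >= e0 & (h + 3600) <= e1), logical(1))

    tr <- trains[trains$site == site, , drop = FALSE]
    pos_min <- integer(0)
    if (nrow(tr) > 0) {
      s <- as.numeric(tr$start)
      e <- s + train_span_s(tr)
      inside <- vapply(seq_along(s), function(i)
        any(s[i] >= e0 & e[i] <= e1), logical(1))
      if (!all(inside))
        stop(sum(!inside), " train(s) at ", site,
             " fall outside all recording-effort intervals")
      m0 <- floor(s / 60)
      m1 <- ceiling(e / 60) - 1
      pos_min <- unique(unlist(lapply(seq_along(s), function(i)
        m0[i]:m1[i])))
    }
    cnt <- table(factor(floor(pos_min / 60) * 3600, levels = hours))
    out[[site]] <- data.frame(
      site = site,
      hour_start = as.POSIXct(hours, origin = "1970-01-01", tz = EST_TZ),
      minutes_detected = as.integer(cnt),
      complete = complete)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Porpoise-positive-hour flags
#'
#' An hour is porpoise-positive (PPH) when at least one click train was
#' detected in it, i.e. `minutes_detected >= 1`.
#'
#' @param hours detection-hour data frame from [bin_hourly()] (complete
#'   hours).
#' @return logical vector, one flag per row.
#' @export
pph_flags <- function(hours) {
  hours$minutes_detected >= 1
}

#' Monthly acoustic detection metrics
#'
#' Aggregates complete detection hours to the four per-month metrics
#' compared against habitat-based density predictions: median
#' porpoise-positive hours (PPH) per day, total PPH, maximum PPH per day,
#' and the proportion of recording days with at least one PPH.  A
#' recording day is a calendar day with at least one complete hour.
#' Months with zero recording days are omitted.
#'
#' @param hours detection-hour data frame; incomplete hours are dropped.
#' @param pool_years if `TRUE` (default) data from all years are pooled
#'   into calendar months 1--12 (matching climatological monthly density
#'   products); otherwise months are kept per year.
#' @return data frame with `site`, `month` (and `year` if not pooling),
#'   `median_pph_per_day`, `total_pph`, `max_pph_per_day`,
#'   `proportion_days_present`, `n_recording_days`.
#' @export
monthly_metrics <- function(hours, pool_years = TRUE) {
  h <- hours[hours$complete, , drop = FALSE]
  if (nrow(h) == 0) stop("no complete hours")
  h$pph <- pph_flags(h)
  h$date <- as.Date(format(h$hour_start, "%Y-%m-%d", tz = EST_TZ))
  daily <- aggregate(pph ~ site + date, data = h, FUN = sum)
  daily$month <- as.integer(format(daily$date, "%m"))
  daily$year <- as.integer(format(daily$date, "%Y"))
  key <- if (pool_years) c("site", "month") else c("site", "year", "month")
  sp <- split(daily, daily[key], drop = TRUE)
  rows <- lapply(sp, function(d) {
    data.frame(d[1, key, drop = FALSE],
               median_pph_per_day = median(d$pph),
               total_pph = sum(d$pph),
               max_pph_per_day = max(d$pph),
               proportion_days_present = mean(d$pph >= 1),
               n_recording_days = nrow(d))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$site, if (!pool_years) res$year else res$month,
                   res$month), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Weekly occurrence proportions on the ISO-8601 week grid
#'
#' For each site and ISO week, the proportion of complete hours that are
#' porpoise-positive.  Weeks with zero complete hours are omitted.
#'
#' @param hours detection-hour data frame; incomplete hours are dropped.
#' @return data frame with `site`, `iso_year`, `iso_week`,
#'   `proportion_hours_present`, `n_complete_hours`.
#' @export
weekly_occurrence <- function(hours) {
  h <- hours[hours$complete, , drop = FALSE]
  if (nrow(h) == 0) stop("no complete hours")
  h$pph <- pph_flags(h)
  wk <- iso_week(as.Date(format(h$hour_start, "%Y-%m-%d", tz = EST_TZ)))
  h$iso_year <- wk$iso_year
  h$iso_week <- wk$iso_week
  sp <- split(h, h[c("site", "iso_year", "iso_week")], drop = TRUE)
  rows <- lapply(sp, function(d) {
    data.frame(site = d$site[1], iso_year = d$iso_year[1],
               iso_week = d$iso_week[1],
               proportion_hours_present = mean(d$pph),
               n_complete_hours = nrow(d))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$site, res$iso_year, res$iso_week), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# contiguous-run segment ids for the complete hours of each site, used to
# restart the GARMA recursion across gaps (a gap is any jump of more than
# one hour in the complete-hour series)
hourly_segments <- function(hours) {
  stopifnot(all(hours$complete))
  seg <- integer(nrow(hours))
  cur <- 0L
  last_site <- ""
  last_t <- -Inf
  t <- as.numeric(hours$hour_start)
  for (i in seq_len(nrow(hours))) {
    if (hours$site[i] != last_site || t[i] - last_t != 3600) cur <- cur + 1L
    seg[i] <- cur
    last_site <- hours$site[i]
    last_t <- t[i]
  }
  seg
}
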