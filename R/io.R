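# Plain-text interchange formats for every pipeline table.  Click-train
# ICI sequences are serialized as a semicolon-separated list of
# microsecond values; timestamps are written as ISO-8601 in fixed-offset
# EST with microsecond precision.

fmt_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%OS6", tz = EST_TZ)

parse_time <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS",
                                     tz = EST_TZ)

#' Write / read click-train tables
#'
#' CSV columns: `site`, `train_start_iso8601`, `ici_list_us`
#' (semicolon-separated microseconds), `quality`.
#'
#' @param trains click-train data frame with a list column `icis`.
#' @param path file path.
#' @return `read_click_trains()` returns the click-train data frame.
#' @export
write_click_trains <- function(trains, path) {
  df <- data.frame(
    site = trains$site,
    train_start_iso8601 = fmt_time(trains$start),
    ici_list_us = vapply(trains$icis, function(ic)
      paste(sprintf("%.6f", ic), collapse = ";"), character(1)),
    quality = trains$quality)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_click_trains
#' @export
read_click_trains <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(site = df$site,
                    start = parse_time(df$train_start_iso8601),
                    quality = df$quality)
  out$icis <- lapply(strsplit(df$ici_list_us, ";", fixed = TRUE), as.numeric)
  out
}

#' Write / read recording-effort tables
#'
#' CSV columns: `site`, `start`, `end` (ISO-8601, EST).
#' @param effort effort data frame.
#' @param path file path.
#' @export
write_effort <- function(effort, path) {
  write.csv(data.frame(site = effort$site, start = fmt_time(effort$start),
                       end = fmt_time(effort$end)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effort
#' @export
read_effort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(site = df$site, start = parse_time(df$start),
             end = parse_time(df$end))
}

#' Write / read daily environment tables
#'
#' CSV columns: `date`, `sst_c`, `chla_mg_m3`, `moon_frac`.
#' @param env daily environment data frame.
#' @param path file path.
#' @export
write_environment <- function(env, path) {
  write.csv(env, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}

#' Write / read monthly density-prediction tables
#'
#' CSV columns: `site`, `month`, `density_per_100km2`.
#' @param density density data frame.
#' @param path file path.
#' @export
write_density <- function(density, path) {
  write.csv(density, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density
#' @export
read_density <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read hourly detection tables
#'
#' CSV columns: `site`, `hour_start` (ISO-8601 EST), `minutes_detected`,
#' `complete`.
#' @param hours detection-hour data frame.
#' @param path file path.
#' @export
write_hourly <- function(hours, path) {
  write.csv(data.frame(site = hours$site,
                       hour_start = fmt_time(hours$hour_start),
                       minutes_detected = hours$minutes_detected,
                       complete = hours$complete),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hourly
#' @export
read_hourly <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$hour_start <- parse_time(df$hour_start)
  df
}

#' Serialize the synthetic ground truth to JSON
#'
#' @param truth a `synthetic_truth`.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(
    params = truth$params,
    config = unclass(truth$config)[c("seed", "distribution",
                                     "overdispersion_sigma",
                                     "zero_inflation_pi", "ar_phi",
                                     "baseline_rate")],
    hourly = data.frame(site = truth$hourly$site,
                        hour_start = fmt_time(truth$hourly$hour_start),
                        mu = truth$hourly$mu,
                        minutes = truth$hourly$minutes,
                        foraging = truth$hourly$foraging))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       Date = "ISO8601")
  invisible(path)
}
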