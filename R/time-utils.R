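# Calendar helpers shared across modules.  Everything runs in fixed-offset
# EST, so calendar days, hours and minutes are plain arithmetic with no
# daylight-saving corner cases.

#' ISO-8601 week-date assignment
#'
#' Maps calendar dates to ISO-8601 week dates: weeks start on Monday and
#' week 1 is the week containing the year's first Thursday, so early
#' January can belong to the previous ISO year (and late December to the
#' next).
#'
#' @param date a `Date` vector (or something coercible by [as.Date()]).
#' @return data frame with columns `iso_year` and `iso_week` (integers,
#'   week in 1--53).
#' @export
iso_week <- function(date) {
  date <- as.Date(date)
  data.frame(
    iso_year = as.integer(format(date, "%G")),
    iso_week = as.integer(format(date, "%V"))
  )
}

# Julian day (day of year, 1-based) of a timestamp or date
julian_day <- function(x, tz = EST_TZ) {
  if (inherits(x, "POSIXct")) {
    as.integer(format(x, "%j", tz = tz))
  } else {
    as.integer(format(as.Date(x), "%j"))
  }
}

# calendar length (365/366) of the year each timestamp falls in
year_length <- function(x, tz = EST_TZ) {
  yr <- if (inherits(x, "POSIXct")) as.integer(format(x, "%Y", tz = tz))
        else as.integer(format(as.Date(x), "%Y"))
  ifelse(yr %% 4 == 0 & (yr %% 100 != 0 | yr %% 400 == 0), 366L, 365L)
}

# hour of day 0..23 in EST
hour_of_day <- function(x, tz = EST_TZ) {
  as.integer(format(x, "%H", tz = tz))
}

# truncate POSIXct to the start of its hour
floor_hour <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 3600) * 3600,
             origin = "1970-01-01", tz = attr(x, "tzone") %||% EST_TZ)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
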