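# Weekly-scale association of porpoise occurrence with environmental
# covariates: ISO-week medians of SST, log chlorophyll a and nightly lunar
# illumination, joined to the weekly occurrence proportions and modelled
# with a Gaussian GAM (the proportion response is kept Gaussian to match
# the analysis this pipeline reproduces, rather than the more orthodox
# binomial choice).

#' Weekly environmental medians joined to weekly occurrence
#'
#' Computes ISO-week medians of the daily environmental series —
#' chlorophyll a is log-transformed before the median by default
#' (`log_first = FALSE` takes the median first, which differs only under
#' within-week skew) — and joins them to the weekly occurrence records.
#' Days with non-positive chlorophyll are dropped (counted in attribute
#' `n_dropped_chl`); weeks with any missing covariate are dropped
#' (counted in attribute `n_dropped_weeks`).
#'
#' @param weekly weekly occurrence data frame from [weekly_occurrence()].
#' @param daily_env daily environment data frame (`date`, `sst_c`,
#'   `chla_mg_m3`, `moon_frac`).
#' @param log_first log-transform chlorophyll before taking the weekly
#'   median (default) or after.
#' @return data frame with `site`, `iso_year`, `iso_week`,
#'   `proportion_hours_present`, `n_complete_hours`, `median_sst_c`,
#'   `median_ln_chla`, `median_moon_frac`.
#' @export
weekly_medians <- function(weekly, daily_env, log_first = TRUE) {
  env <- daily_env
  bad_chl <- !is.na(env$chla_mg_m3) & env$chla_mg_m3 <= 0
  if (any(bad_chl)) env$chla_mg_m3[bad_chl] <- NA
  wk <- iso_week(env$date)
  env$iso_year <- wk$iso_year
  env$iso_week <- wk$iso_week
  med <- function(x) if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)
  sp <- split(env, env[c("iso_year", "iso_week")], drop = TRUE)
  emed <- do.call(rbind, lapply(sp, function(d) data.frame(
    iso_year = d$iso_year[1], iso_week = d$iso_week[1],
    median_sst_c = med(d$sst_c),
    median_ln_chla = if (log_first) med(log(d$chla_mg_m3))
                     else log(med(d$chla_mg_m3)),
    median_moon_frac = med(d$moon_frac))))
  out <- merge(weekly, emed, by = c("iso_year", "iso_week"), sort = FALSE)
  keep <- complete.cases(out[c("median_sst_c", "median_ln_chla",
                               "median_moon_frac")])
  res <- out[keep, c("site", "iso_year", "iso_week",
                     "proportion_hours_present", "n_complete_hours",
                     "median_sst_c", "median_ln_chla", "median_moon_frac")]
  res <- res[order(res$site, res$iso_year, res$iso_week), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped_chl") <- sum(bad_chl)
  attr(res, "n_dropped_weeks") <- sum(!keep)
  res
}

#' Gaussian GAM of weekly occurrence against environmental covariates
#'
#' Fits Gaussian GAMs of the weekly proportion of porpoise-positive hours
#' on natural-spline smooths of weekly median SST, log chlorophyll a and
#' moon-illuminated fraction, over all covariate subsets, and selects by
#' AIC.  The selected fit reports per-term EDF, deviance explained and
#' adjusted R-squared.
#'
#' @param records weekly records from [weekly_medians()] for one site.
#' @param k basis dimension per smooth.
#' @param min_records minimum number of weekly records required.
#' @return the selected `pam_gam` with an extra `candidates` AIC table.
#' @export
env_gam <- function(records, k = 10, min_records = 30) {
  if (nrow(records) < min_records)
    stop("only ", nrow(records), " weekly records; at least ", min_records,
         " required")
  d <- data.frame(prop = records$proportion_hours_present,
                  sst = records$median_sst_c,
                  lnchla = records$median_ln_chla,
                  moon = records$median_moon_frac)
  vars <- c("sst", "lnchla", "moon")
  usable <- vars[vapply(vars, function(v) length(unique(d[[v]])) >= k,
                        logical(1))]
  subsets <- list(character(0))
  for (v in usable) subsets <- c(subsets, lapply(subsets, c, v))
  names(subsets) <- vapply(subsets, function(s)
    if (length(s)) paste(s, collapse = "+") else "intercept", character(1))
  fits <- lapply(subsets, function(s)
    fit_gam(d, "prop", lapply(s, s_spline, k = k), family = "gaussian"))
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  edfs <- vapply(fits, function(f) f$edf_total, numeric(1))
  best <- fits[[order(aics, edfs)[1]]]
  best$candidates <- data.frame(model = names(subsets), aic = aics,
                                edf = edfs, row.names = NULL)
  best
}
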