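# Configuration for the synthetic C-POD data generator.  The defaults
# describe the monitored system the pipeline is built for: four
# bottom-moored detectors off the mid-Atlantic coast recording from
# November 2014 to May 2016, a winter--spring occupancy peak, an
# evening--morning diel peak, over-dispersed zero-heavy hourly counts,
# foraging buzzes with inter-click intervals under 10 ms, and
# instrument-loss gaps at two sites.

#' Build a synthetic C-POD simulation configuration
#'
#' @param site_ids site labels.
#' @param start_date,end_date calendar dates spanned by the simulated
#'   recording (inclusive).
#' @param baseline_rate expected detection-positive minutes per hour at the
#'   seasonal/diel average (the log-link intercept is `log(baseline_rate)`);
#'   scalar or one value per site.
#' @param seasonal_amplitude,seasonal_peak_day amplitude (log scale,
#'   dimensionless) and Julian-day phase of the annual occupancy cycle.
#' @param diel_amplitude,diel_peak_hour amplitude (log scale) and peak hour
#'   (EST, 0--23) of the daily occupancy cycle.
#' @param ar_phi AR(1) feedback coefficient of the link-scale recursion
#'   used when generating the hourly series (0 disables feedback).
#' @param distribution conditional count distribution: `"pig"`, `"poisson"`
#'   or `"zip"`.
#' @param overdispersion_sigma PIG dispersion (`>= 0`; variance
#'   `mu(1 + sigma*mu)`).
#' @param zero_inflation_pi ZIP zero-inflation probability in `[0, 1)`.
#' @param foraging_prob_curve length-24 vector: probability that a
#'   detection-positive hour starting at each hour of day contains a
#'   foraging buzz.
#' @param travel_ici_range,buzz_ici_range inter-click-interval ranges in
#'   microseconds for travelling trains (lower bound must exceed the 10 ms
#'   buzz threshold) and buzz sequences (upper bound at most 10,000 us).
#' @param buzz_run_length number of consecutive buzz ICIs inserted into the
#'   buzz train of a foraging hour (>= 5 so foraging hours carry a clear
#'   buzz signature).
#' @param quality_class_probs probabilities of the Hi/Med/Low train quality
#'   classes; must sum to 1.
#' @param gap_schedule list of recording outages, each
#'   `list(site =, start =, end =)` with inclusive dates; these hours carry
#'   no effort and no trains.
#' @param env_params list of environmental-series parameters: SST annual
#'   sinusoid (`sst_mean_c`, `sst_amplitude_c`, `sst_peak_day`),
#'   chlorophyll bloom (`chl_baseline`, `chl_bloom_peak` in mg m^-3,
#'   `chl_bloom_start`/`chl_bloom_end` as Julian days) and
#'   `moon_period_days` for the rectified-cosine lunar cycle.
#' @param density_noise_sd log-scale noise of the synthetic monthly density
#'   predictions (0 gives a noise-free monotone link to monthly occupancy).
#' @param seed integer seed; every generator stage derives its RNG stream
#'   from it, so equal seeds give byte-identical outputs.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(site_ids = paste0("site", 1:4),
                       start_date = as.Date("2014-11-04"),
                       end_date = as.Date("2016-05-18"),
                       baseline_rate = c(0.06, 0.08, 0.12, 0.015),
                       seasonal_amplitude = 1.8,
                       seasonal_peak_day = 46,
                       diel_amplitude = 0.5,
                       diel_peak_hour = 22,
                       ar_phi = 0.25,
                       distribution = c("pig", "poisson", "zip"),
                       overdispersion_sigma = 0.5,
                       zero_inflation_pi = 0,
                       foraging_prob_curve =
                         plogis(0.4 + 1.1 * cos(2 * pi * (0:23 - 23) / 24)),
                       travel_ici_range = c(30000, 120000),
                       buzz_ici_range = c(1500, 8000),
                       buzz_run_length = 6,
                       quality_class_probs = c(Hi = 0.5, Med = 0.3, Low = 0.2),
                       gap_schedule = list(
                         list(site = "site2", start = as.Date("2016-02-29"),
                              end = as.Date("2016-05-18")),
                         list(site = "site4", start = as.Date("2014-11-04"),
                              end = as.Date("2015-04-22")),
                         list(site = "site4", start = as.Date("2016-02-28"),
                              end = as.Date("2016-05-18"))
                       ),
                       env_params = list(
                         sst_mean_c = 15, sst_amplitude_c = 10,
                         sst_peak_day = 220,
                         chl_baseline = 0.8, chl_bloom_peak = 6,
                         chl_bloom_start = 10, chl_bloom_end = 110,
                         moon_period_days = 29.53
                       ),
                       density_noise_sd = 0.6,
                       seed = 1L) {
  distribution <- match.arg(distribution)
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (!(end_date > start_date)) stop("'end_date' must be after 'start_date'")
  if (abs(sum(quality_class_probs) - 1) > 1e-12)
    stop("'quality_class_probs' must sum to 1")
  if (!all(c("Hi", "Med", "Low") %in% names(quality_class_probs)))
    stop("'quality_class_probs' needs named entries Hi, Med, Low")
  if (buzz_ici_range[2] > 10000)
    stop("'buzz_ici_range' upper bound must be <= 10,000 microseconds")
  if (travel_ici_range[1] <= 10000)
    stop("'travel_ici_range' lower bound must exceed 10,000 microseconds")
  if (length(foraging_prob_curve) != 24 ||
      any(foraging_prob_curve < 0 | foraging_prob_curve > 1))
    stop("'foraging_prob_curve' must be 24 probabilities")
  if (overdispersion_sigma < 0) stop("'overdispersion_sigma' must be >= 0")
  if (zero_inflation_pi < 0 || zero_inflation_pi >= 1)
    stop("'zero_inflation_pi' must be in [0, 1)")
  if (buzz_run_length < 5)
    stop("'buzz_run_length' must be at least 5")
  baseline_rate <- rep_len(baseline_rate, length(site_ids))
  names(baseline_rate) <- site_ids
  for (g in gap_schedule)
    if (!g$site %in% site_ids) stop("gap site '", g$site, "' not in site_ids")
  structure(list(
    site_ids = site_ids, start_date = start_date, end_date = end_date,
    baseline_rate = baseline_rate,
    seasonal_amplitude = seasonal_amplitude,
    seasonal_peak_day = seasonal_peak_day,
    diel_amplitude = diel_amplitude, diel_peak_hour = diel_peak_hour,
    ar_phi = ar_phi, distribution = distribution,
    overdispersion_sigma = overdispersion_sigma,
    zero_inflation_pi = zero_inflation_pi,
    foraging_prob_curve = foraging_prob_curve,
    travel_ici_range = travel_ici_range, buzz_ici_range = buzz_ici_range,
    buzz_run_length = buzz_run_length,
    quality_class_probs = quality_class_probs,
    gap_schedule = gap_schedule, env_params = env_params,
    density_noise_sd = density_noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Recording-effort table implied by a simulation configuration
#'
#' Expands the configured date range minus the gap schedule into
#' non-overlapping effort intervals per site (half-open, in EST).
#'
#' @param config a [sim_config()].
#' @return data frame with columns `site`, `start`, `end` (`POSIXct`).
#' @export
effort_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = EST_TZ)
  t1 <- as.POSIXct(paste(config$end_date + 1, "00:00:00"), tz = EST_TZ)
  out <- list()
  for (site in config$site_ids) {
    gaps <- Filter(function(g) g$site == site, config$gap_schedule)
    cuts <- data.frame(start = t0, end = t1)
    for (g in gaps) {
      gs <- as.POSIXct(paste(as.Date(g$start), "00:00:00"), tz = EST_TZ)
      ge <- as.POSIXct(paste(as.Date(g$end) + 1, "00:00:00"), tz = EST_TZ)
      nxt <- list()
      for (i in seq_len(nrow(cuts))) {
        s <- cuts$start[i]; e <- cuts$end[i]
        if (ge <= s || gs >= e) { nxt[[length(nxt) + 1]] <- c(s, e); next }
        if (gs > s) nxt[[length(nxt) + 1]] <- c(s, min(gs, e))
        if (ge < e) nxt[[length(nxt) + 1]] <- c(max(ge, s), e)
      }
      cuts <- if (length(nxt)) {
        do.call(rbind.data.frame,
                lapply(nxt, function(v) data.frame(start = v[1], end = v[2])))
      } else data.frame(start = t0[0], end = t1[0])
    }
    if (nrow(cuts))
      out[[site]] <- data.frame(site = site, cuts, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$start <- as.POSIXct(res$start, origin = "1970-01-01", tz = EST_TZ)
  res$end <- as.POSIXct(res$end, origin = "1970-01-01", tz = EST_TZ)
  res
}
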