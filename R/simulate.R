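# Synthetic C-POD data generator.  Draws hourly detection-positive minute
# counts from the same GARMA family the fitters estimate, expands positive
# minutes into click trains with travelling or buzz inter-click intervals,
# and emits the companion environmental and monthly-density tables.  The
# ground truth (latent means, realized minutes, foraging flags, generating
# parameters) is retained so downstream stages can be tested exactly.
#
# RNG discipline: each stage seeds its own stream from `config$seed` plus
# a fixed stage offset, so any stage can be re-run individually and equal
# seeds give byte-identical tables.

# generating regression coefficients implied by the configured amplitudes
# and phases, in the sin/cos basis of harmonic_design() for year length d
sim_beta <- function(config, baseline, d) {
  a_s <- config$seasonal_amplitude
  a_d <- config$diel_amplitude
  c(log(baseline),
    sin_hour = a_d * sin(2 * pi * config$diel_peak_hour / 24),
    cos_hour = a_d * cos(2 * pi * config$diel_peak_hour / 24),
    sin_jday = a_s * sin(2 * pi * config$seasonal_peak_day / d),
    cos_jday = a_s * cos(2 * pi * config$seasonal_peak_day / d))
}

#' Simulate the hourly occupancy series with ground truth
#'
#' Draws, for every recorded hour at every site, the number of
#' detection-positive minutes from the configured count distribution
#' (Poisson, PIG or ZIP) with log-link mean driven by diel and seasonal
#' sinusoids plus optional AR(1) link-scale feedback — the same model
#' family [fit_garma()] estimates.  Counts are generated in a regime where
#' exceeding 60 is vanishingly rare (configurations whose expected mean
#' exceeds 60 minutes are rejected) and then capped at the 60-minute
#' ceiling.  Foraging flags are drawn per detection-positive hour from the
#' configured hour-of-day probability curve.
#'
#' @param config a [sim_config()].
#' @return an object of class `"synthetic_truth"`: `hourly` data frame
#'   (`site`, `hour_start`, `segment`, `mu`, `minutes`, `foraging`), the
#'   generating parameters per site, and the configuration.
#' @export
simulate_occupancy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  eff <- effort_table(config)
  out <- list()
  params <- list()
  for (site in config$site_ids) {
    es <- eff[eff$site == site, , drop = FALSE]
    if (nrow(es) == 0) next
    hours <- do.call(c, lapply(seq_len(nrow(es)), function(i)
      seq(es$start[i], es$end[i] - 3600, by = 3600)))
    attr(hours, "tzone") <- EST_TZ
    segment <- rep(seq_len(nrow(es)),
                   vapply(seq_len(nrow(es)), function(i)
                     as.integer(difftime(es$end[i], es$start[i],
                                         units = "hours")), integer(1)))
    X <- harmonic_design(hours)
    # phases are defined against each year's own calendar length; use the
    # length of the first year for the fixed beta (the basis itself uses
    # the per-year length, so the peak day drifts by < 1 day in leap years)
    d0 <- year_length(hours[1])
    beta <- sim_beta(config, config$baseline_rate[[site]], d0)
    xb <- drop(X %*% beta)
    if (max(exp(xb)) > 60)
      stop("configured amplitudes give an expected mean above 60 ",
           "minutes/hour (max ", round(max(exp(xb)), 1),
           "); reduce baseline_rate or the amplitudes")
    n <- length(hours)
    y <- numeric(n); mu <- numeric(n)
    phi <- config$ar_phi
    cc <- 0.1
    for (t in seq_len(n)) {
      e <- xb[t]
      if (phi != 0 && t > 1 && segment[t - 1] == segment[t])
        e <- e + phi * (log(max(y[t - 1], cc)) - xb[t - 1])
      mu[t] <- exp(e)
      y[t] <- switch(config$distribution,
        poisson = rpois(1, mu[t]),
        pig = rpig(1, mu[t], config$overdispersion_sigma),
        zip = rzip(1, mu[t], config$zero_inflation_pi))
    }
    y <- pmin(y, 60)
    hod <- hour_of_day(hours)
    foraging <- y > 0 & runif(n) < config$foraging_prob_curve[hod + 1]
    out[[site]] <- data.frame(site = site, hour_start = hours,
                              segment = segment, mu = mu,
                              minutes = as.integer(y), foraging = foraging)
    params[[site]] <- list(beta = beta, phi = phi,
                           sigma = config$overdispersion_sigma,
                           pi = config$zero_inflation_pi,
                           distribution = config$distribution)
  }
  hourly <- do.call(rbind, out)
  rownames(hourly) <- NULL
  structure(list(hourly = hourly, params = params, config = config),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d sites, %d recorded hours, %s counts\n",
              length(unique(x$hourly$site)), nrow(x$hourly),
              x$config$distribution))
  cat(sprintf("  positive hours: %d (%.1f%%), foraging hours: %d\n",
              sum(x$hourly$minutes > 0),
              100 * mean(x$hourly$minutes > 0), sum(x$hourly$foraging)))
  invisible(x)
}

# one train's inter-click intervals (microseconds)
sim_train_icis <- function(config, buzz) {
  n_travel <- 4 + rpois(1, 4)
  icis <- runif(n_travel, config$travel_ici_range[1],
                config$travel_ici_range[2])
  if (buzz) {
    run <- runif(config$buzz_run_length, config$buzz_ici_range[1],
                 config$buzz_ici_range[2])
    at <- sample.int(n_travel + 1, 1) - 1
    icis <- append(icis, run, after = at)
  }
  icis
}

#' Expand the occupancy truth into click-train logs
#'
#' Every detection-positive minute receives one train whose quality class
#' is Hi or Med (so quality filtering cannot erase a positive minute),
#' plus a Poisson number of additional Low-quality trains chosen so the
#' marginal Hi/Med/Low frequencies match `quality_class_probs`.  In hours
#' flagged as foraging, one train contains a run of at least five buzz
#' ICIs drawn from `buzz_ici_range` (all at most 10,000 us); all other
#' ICIs come from `travel_ici_range`.  Trains are placed so that each
#' train lies entirely within its minute, which keeps the minute-binning
#' round trip exact.
#'
#' @param truth a `synthetic_truth` from [simulate_occupancy()].
#' @param config the same [sim_config()] used to generate `truth`.
#' @return data frame of click trains: `site`, `start` (`POSIXct`, EST),
#'   `icis` (list column, microseconds), `quality`.
#' @export
simulate_click_trains <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  hp <- truth$hourly[truth$hourly$minutes > 0, , drop = FALSE]
  pq <- config$quality_class_probs
  p_hi_med <- pq[c("Hi", "Med")] / sum(pq[c("Hi", "Med")])
  lam_low <- pq[["Low"]] / (1 - pq[["Low"]])
  site <- character(); start <- numeric(); quality <- character()
  icis <- list()
  for (i in seq_len(nrow(hp))) {
    m <- hp$minutes[i]
    mins <- sort(sample.int(60, m) - 1)
    buzz_minute <- if (hp$foraging[i]) mins[sample.int(m, 1)] else -1
    h0 <- as.numeric(hp$hour_start[i])
    for (mn in mins) {
      tr_icis <- sim_train_icis(config, buzz = mn == buzz_minute)
      span <- sum(tr_icis) / 1e6
      off <- runif(1, 0, max(60 - span - 0.01, 0))
      site <- c(site, hp$site[i])
      start <- c(start, h0 + mn * 60 + off)
      quality <- c(quality, sample(names(p_hi_med), 1, prob = p_hi_med))
      icis[[length(icis) + 1]] <- tr_icis
      for (k in seq_len(rpois(1, lam_low))) {
        lo_icis <- sim_train_icis(config, buzz = FALSE)
        lo_span <- sum(lo_icis) / 1e6
        site <- c(site, hp$site[i])
        start <- c(start, h0 + mn * 60 +
                     runif(1, 0, max(60 - lo_span - 0.01, 0)))
        quality <- c(quality, "Low")
        icis[[length(icis) + 1]] <- lo_icis
      }
    }
  }
  trains <- data.frame(site = site,
                       start = as.POSIXct(start, origin = "1970-01-01",
                                          tz = EST_TZ),
                       quality = quality)
  trains$icis <- icis
  ord <- order(trains$site, trains$start)
  trains <- trains[ord, , drop = FALSE]
  rownames(trains) <- NULL
  trains
}

#' Simulate the daily environmental series
#'
#' Deterministic daily series shared by all sites: SST follows the
#' configured annual sinusoid, chlorophyll a follows a baseline with a
#' raised-cosine winter--spring bloom window, and the nightly
#' moon-illuminated fraction is a rectified cosine with the configured
#' synodic period.
#'
#' @param config a [sim_config()].
#' @return data frame with `date`, `sst_c`, `chla_mg_m3`, `moon_frac`.
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ep <- config$env_params
  dates <- seq(config$start_date, config$end_date, by = "day")
  jd <- julian_day(dates)
  d <- year_length(dates)
  sst <- ep$sst_mean_c +
    ep$sst_amplitude_c * cos(2 * pi * (jd - ep$sst_peak_day) / d)
  in_bloom <- jd >= ep$chl_bloom_start & jd <= ep$chl_bloom_end
  w <- numeric(length(jd))
  span <- ep$chl_bloom_end - ep$chl_bloom_start
  w[in_bloom] <- 0.5 * (1 - cos(2 * pi * (jd[in_bloom] - ep$chl_bloom_start) /
                                  span))
  chl <- ep$chl_baseline + (ep$chl_bloom_peak - ep$chl_baseline) * w
  tday <- as.numeric(dates - dates[1])
  moon <- abs(cos(pi * tday / ep$moon_period_days))
  data.frame(date = dates, sst_c = sst, chla_mg_m3 = chl, moon_frac = moon)
}

#' Simulate monthly habitat-based density predictions
#'
#' Emulates an external habitat-model product: per site, twelve monthly
#' densities (individuals per 100 km^2) obtained as a monotone transform
#' of the true monthly mean detection-positive minutes (pooled across
#' years), optionally degraded with log-normal noise.  Months the site
#' never recorded are filled from the latent mean instead, since a
#' habitat model predicts every month regardless of acoustic effort.
#'
#' @param truth a `synthetic_truth`.
#' @param noise_sd log-scale noise standard deviation; defaults to the
#'   configuration's `density_noise_sd`.  With `noise_sd = 0` the rank
#'   order of the densities equals the rank order of true monthly mean
#'   occupancy.
#' @return data frame with `site`, `month` (1--12), `density_per_100km2`.
#' @export
simulate_density_predictions <- function(truth, noise_sd = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  config <- truth$config
  if (is.null(noise_sd)) noise_sd <- config$density_noise_sd
  set.seed(config$seed + 3L)
  hh <- truth$hourly
  hh$month <- as.integer(format(hh$hour_start, "%m", tz = EST_TZ))
  out <- list()
  for (site in unique(hh$site)) {
    hs <- hh[hh$site == site, ]
    occ <- tapply(hs$minutes, hs$month, mean)
    lat <- tapply(hs$mu, hs$month, mean)
    months <- 1:12
    v <- rep(NA_real_, 12)
    v[as.integer(names(occ))] <- occ
    miss <- is.na(v)
    if (any(miss)) {
      # latent fill, shifted below the observed scale only if needed to
      # stay monotone-consistent is not required: missing months are
      # dropped pairwise during validation anyway
      v[miss] <- lat[match(months[miss], as.integer(names(lat)))]
      v[is.na(v)] <- 0
    }
    dens <- 30 * (v / max(v, 1e-9))^0.8
    if (noise_sd > 0) dens <- dens * exp(rnorm(12, 0, noise_sd))
    out[[site]] <- data.frame(site = site, month = months,
                              density_per_100km2 = dens)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
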