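# Synthetic C-POD generator: distributional checks, construction
# guarantees, determinism.

test_that("homogeneous Poisson configuration gives the configured mean", {
  cfg <- flat_config(n_days = 417, baseline = 3, dist = "poisson", seed = 2)
  truth <- simulate_occupancy(cfg)
  y <- truth$hourly$minutes[1:10000]
  expect_lt(abs(mean(y) - 3), 4 * sqrt(3 / 10000))
})

test_that("zero baseline gives an all-zero series", {
  cfg <- flat_config(n_days = 10, baseline = 1e-12, dist = "zip",
                     pi0 = 0.5, seed = 3)
  truth <- simulate_occupancy(cfg)
  expect_true(all(truth$hourly$minutes == 0))
})

test_that("PIG occupancy counts match the mean-dispersion variance
           formula", {
  cfg <- flat_config(n_days = 834, baseline = 5, dist = "pig",
                     sigma = 0.5, seed = 4)
  truth <- simulate_occupancy(cfg)
  y <- truth$hourly$minutes[1:20000]
  expect_lt(abs(var(y) - 17.5) / 17.5, 0.10)
  expect_lt(abs(mean(y) - 5) / 5, 0.05)
})

test_that("configurations implying means above the 60-minute ceiling are
           rejected", {
  cfg <- flat_config(n_days = 30, baseline = 50, seed = 5)
  cfg$seasonal_amplitude <- 2   # exp(log 50 + 2) >> 60
  expect_error(simulate_occupancy(cfg), "60")
})

test_that("realized minutes stay within 0..60 and latent means are
           positive", {
  truth <- simulate_occupancy(sim_config(seed = 6))
  expect_true(all(truth$hourly$minutes >= 0 & truth$hourly$minutes <= 60))
  expect_true(all(truth$hourly$mu > 0))
})

test_that("click trains respect foraging flags, minute placement and the
           train definition", {
  cfg <- flat_config(n_days = 40, baseline = 1.5, seed = 7)
  truth <- simulate_occupancy(cfg)
  trains <- simulate_click_trains(truth, cfg)
  expect_true(all(vapply(trains$icis, length, integer(1)) >= 4))
  expect_true(all(unlist(trains$icis) > 0))
  th <- floor(as.numeric(trains$start) / 3600) * 3600
  key <- paste(trains$site, th)
  hr <- truth$hourly
  hkey <- paste(hr$site, as.numeric(hr$hour_start))
  # no trains in zero-minute hours
  expect_true(all(key %in% hkey[hr$minutes > 0]))
  # foraging hours contain a buzz ICI; non-foraging hours do not
  min_ici <- tapply(vapply(trains$icis, min, numeric(1)), key, min)
  for (i in which(hr$minutes > 0)) {
    mi <- min_ici[[hkey[i]]]
    if (hr$foraging[i]) expect_lte(mi, 10000) else expect_gt(mi, 10000)
  }
})

test_that("quality-class frequencies fall within exact binomial 99%
           bounds", {
  cfg <- flat_config(n_days = 100, baseline = 1.5, seed = 8)
  truth <- simulate_occupancy(cfg)
  trains <- simulate_click_trains(truth, cfg)
  n <- nrow(trains)
  expect_gt(n, 1000)
  probs <- cfg$quality_class_probs
  freq <- table(factor(trains$quality, levels = names(probs)))
  for (cl in names(probs)) {
    lo <- qbinom(0.005, n, probs[[cl]])
    hi <- qbinom(0.995, n, probs[[cl]])
    expect_gte(freq[[cl]], lo)
    expect_lte(freq[[cl]], hi)
  }
})

test_that("no trains are emitted inside scheduled gaps", {
  cfg <- sim_config(seed = 9)
  truth <- simulate_occupancy(cfg)
  trains <- simulate_click_trains(truth, cfg)
  for (g in cfg$gap_schedule) {
    gs <- as.POSIXct(paste(g$start, "00:00:00"), tz = est_tz())
    ge <- as.POSIXct(paste(g$end + 1, "00:00:00"), tz = est_tz())
    inside <- trains$site == g$site & trains$start >= gs & trains$start < ge
    expect_equal(sum(inside), 0)
  }
})

test_that("generator output is byte-identical across runs with the same
           seed", {
  cfg <- flat_config(n_days = 20, baseline = 1, seed = 10)
  t1 <- simulate_occupancy(cfg)
  t2 <- simulate_occupancy(cfg)
  expect_identical(t1$hourly, t2$hourly)
  expect_identical(simulate_click_trains(t1, cfg),
                   simulate_click_trains(t2, cfg))
  expect_identical(simulate_environment(cfg), simulate_environment(cfg))
  expect_identical(simulate_density_predictions(t1),
                   simulate_density_predictions(t2))
})

test_that("environmental series follow their configured shapes", {
  cfg <- sim_config(seed = 11)
  cfg$env_params$sst_amplitude_c <- 0
  env0 <- simulate_environment(cfg)
  expect_true(all(env0$sst_c == cfg$env_params$sst_mean_c))

  cfg2 <- sim_config(seed = 11)
  env <- simulate_environment(cfg2)
  expect_true(all(env$moon_frac >= 0 & env$moon_frac <= 1))
  peaks <- which(diff(sign(diff(env$moon_frac))) == -2) + 1
  expect_true(all(diff(env$date[peaks]) %in% c(29, 30)))
  # chlorophyll outside the bloom window sits at baseline (July value)
  july <- env$chla_mg_m3[format(env$date, "%m") == "07"]
  expect_true(all(july == cfg2$env_params$chl_baseline))
})

test_that("noise-free density predictions rank-match true monthly
           occupancy; permutation destroys the correlation", {
  cfg <- flat_config(n_days = 365, baseline = 0.8, seed = 12)
  cfg$seasonal_amplitude <- 1.5
  truth <- simulate_occupancy(cfg)
  dens <- simulate_density_predictions(truth, noise_sd = 0)
  hh <- truth$hourly
  hh$month <- as.integer(format(hh$hour_start, "%m", tz = est_tz()))
  occ <- tapply(hh$minutes, hh$month, mean)
  rho <- spearman(occ[as.character(dens$month)], dens$density_per_100km2)
  expect_equal(rho$rho, 1, tolerance = 1e-12)
  set.seed(99)
  perm_rhos <- replicate(200, {
    spearman(sample(occ), dens$density_per_100km2)$rho
  })
  expect_lt(abs(mean(perm_rhos)), 0.1)
})

test_that("noisy density predictions agree with a direct Monte-Carlo
           oracle of the expected Spearman correlation", {
  cfg <- flat_config(n_days = 365, baseline = 0.8, seed = 13)
  cfg$seasonal_amplitude <- 1.5
  truth <- simulate_occupancy(cfg)
  hh <- truth$hourly
  hh$month <- as.integer(format(hh$hour_start, "%m", tz = est_tz()))
  occ <- tapply(hh$minutes, hh$month, mean)
  ns <- cfg$density_noise_sd
  # package route: vary the density stage's seed, truth held fixed
  pkg_rhos <- vapply(1:200, function(r) {
    tr <- truth; tr$config$seed <- 1000L + r
    d <- simulate_density_predictions(tr)
    spearman(occ[as.character(d$month)], d$density_per_100km2)$rho
  }, numeric(1))
  # independent Monte-Carlo oracle on the same monotone link
  set.seed(77)
  base <- 30 * (occ / max(occ))^0.8
  ora_rhos <- replicate(400, {
    d <- base * exp(rnorm(12, 0, ns))
    cor(rank(occ), rank(d))
  })
  expect_lt(abs(mean(pkg_rhos) - mean(ora_rhos)), 0.1)
})
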