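# Shared fixtures and independent oracles, built in code at test time.

EST <- "Etc/GMT+5"

est_time <- function(s) as.POSIXct(s, tz = EST)

# a click train row; `icis` in microseconds
train_row <- function(site, start, icis, quality) {
  df <- data.frame(site = site, start = est_time(start), quality = quality)
  df$icis <- list(icis)
  df
}

# Hand-built 3-day fixture (one site, 2015-03-01 .. 2015-03-03, complete
# effort) with every downstream quantity worked out by hand:
#  train 1: 10:05:30 + 40 s  -> minutes 5,6 of hour 10
#  train 2: 10:06:05 + 10 s  -> minute 6 again (counted once)
#  train 3: 23:59:50 + 5 s   -> minute 59 of hour 23; contains one 9 ms
#           buzz ICI, so hour 23 is foraging positive
#  train 4: day 2, 00:30:00 + exactly 60 s -> minute 30 only (half-open)
#  train 5: day 2, 05:00:10, Low quality   -> removed by the filter
#  train 6: day 3, 12:00:00 + 120 s        -> minutes 0,1 of hour 12
# PPH per day: {2, 1, 1}; monthly: median 1, total 4, max 2, prop 1;
# ISO weeks: 2015-W09 has 24 complete hours with 2 PPH, 2015-W10 has 48
# with 2 PPH.
hand_fixture <- function() {
  trains <- rbind(
    train_row("A", "2015-03-01 10:05:30", rep(1e6, 40), "Hi"),
    train_row("A", "2015-03-01 10:06:05", rep(1e6, 10), "Med"),
    train_row("A", "2015-03-01 23:59:50", c(9000, rep(1e6, 4), 991000),
              "Hi"),
    train_row("A", "2015-03-02 00:30:00", rep(1e6, 60), "Hi"),
    train_row("A", "2015-03-02 05:00:10", rep(1e6, 10), "Low"),
    train_row("A", "2015-03-03 12:00:00", rep(2e6, 60), "Med"))
  effort <- data.frame(site = "A",
                       start = est_time("2015-03-01 00:00:00"),
                       end = est_time("2015-03-04 00:00:00"))
  list(trains = trains, effort = effort)
}

# independent ISO week-date oracle: pure date arithmetic via the Thursday
# rule (week 1 contains the year's first Thursday; weeks start Monday)
iso_week_oracle <- function(date) {
  date <- as.Date(date)
  days <- as.numeric(date)                    # 1970-01-01 was a Thursday
  dow <- ((days + 3) %% 7) + 1                # ISO weekday, Mon = 1
  thursday <- date + (4 - dow)
  iso_year <- as.integer(format(thursday, "%Y"))
  jan1 <- as.Date(paste0(iso_year, "-01-01"))
  week <- as.integer((as.numeric(thursday) - as.numeric(jan1)) %/% 7 + 1)
  data.frame(iso_year = iso_year, iso_week = week)
}

# brute-force Spearman oracle: rank formula plus exhaustive permutation p
spearman_bruteforce <- function(x, y) {
  rho_of <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  n <- length(x)
  rho <- rho_of(x, y)
  perm_rhos <- apply(all_perms(n), 1, function(p) rho_of(x, y[p]))
  list(rho = rho, p = mean(abs(perm_rhos) >= abs(rho) - 1e-12))
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(((1:n)[-i])[sub], nrow(sub)))
  }))
}

# exhaustive pairwise AUC oracle
auc_bruteforce <- function(observed, scores) {
  pos <- scores[observed == 1]
  neg <- scores[observed == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# minimal simulation configs for fast tests
flat_config <- function(n_days, baseline, dist = "poisson", sigma = 0,
                        pi0 = 0, ar = 0, seed = 1, ...) {
  sim_config(site_ids = "s1",
             start_date = as.Date("2015-01-01"),
             end_date = as.Date("2015-01-01") + n_days - 1,
             baseline_rate = baseline,
             seasonal_amplitude = 0, diel_amplitude = 0,
             ar_phi = ar, distribution = dist,
             overdispersion_sigma = sigma, zero_inflation_pi = pi0,
             gap_schedule = list(), seed = seed, ...)
}
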