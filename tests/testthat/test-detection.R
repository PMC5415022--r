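# Detection processing: quality filter, minute binning, monthly metrics,
# ISO weeks, weekly occurrence.

test_that("quality filter keeps Hi and Med in order and rejects unknown
           labels with a count", {
  tr <- rbind(train_row("A", "2015-03-01 01:00:00", rep(5e4, 5), "Hi"),
              train_row("A", "2015-03-01 02:00:00", rep(5e4, 5), "Low"),
              train_row("A", "2015-03-01 03:00:00", rep(5e4, 5), "Med"),
              train_row("A", "2015-03-01 04:00:00", rep(5e4, 5), "Low"))
  out <- filter_trains(tr)
  expect_equal(out$quality, c("Hi", "Med"))
  expect_true(all(diff(as.numeric(out$start)) > 0))

  expect_equal(nrow(filter_trains(tr[tr$quality == "Low", ])), 0)
  expect_equal(nrow(filter_trains(tr[0, ])), 0)

  tr$quality[2] <- "Junk"
  expect_warning(out2 <- filter_trains(tr), "unknown quality")
  expect_equal(attr(out2, "n_unknown_quality"), 1)
})

test_that("minute binning covers exactly the overlapped minutes with
           half-open conventions", {
  eff <- data.frame(site = "A", start = est_time("2015-03-01 10:00:00"),
                    end = est_time("2015-03-01 12:00:00"))
  # spans 10:05:30 -> 10:06:10: minutes 5 and 6
  tr <- train_row("A", "2015-03-01 10:05:30", rep(1e6, 40), "Hi")
  h <- bin_hourly(tr, eff)
  expect_equal(h$minutes_detected[h$hour_start == est_time("2015-03-01 10:00:00")], 2L)

  # two overlapping trains in one minute count once
  tr2 <- rbind(tr, train_row("A", "2015-03-01 10:05:35", rep(1e6, 10), "Hi"))
  h2 <- bin_hourly(tr2, eff)
  expect_equal(h2$minutes_detected[1], 2L)

  # a train ending exactly on a minute boundary does not enter the next
  tr3 <- train_row("A", "2015-03-01 11:30:00", rep(1e6, 60), "Hi")
  h3 <- bin_hourly(tr3, eff)
  expect_equal(h3$minutes_detected[h3$hour_start == est_time("2015-03-01 11:00:00")], 1L)

  # trains outside all effort error out
  tr4 <- train_row("A", "2015-03-01 13:00:00", rep(1e6, 10), "Hi")
  expect_error(bin_hourly(tr4, eff), "outside")
})

test_that("hours only partially covered by effort are marked incomplete", {
  eff <- data.frame(site = "A", start = est_time("2015-03-01 10:00:00"),
                    end = est_time("2015-03-01 10:30:00"))
  tr <- train_row("A", "2015-03-01 10:05:30", rep(1e6, 40), "Hi")
  h <- bin_hourly(tr, eff)
  expect_false(any(h$complete))
  expect_equal(h$minutes_detected[1], 2L)
})

test_that("pph flags are exactly the minutes >= 1 indicator", {
  h <- data.frame(minutes_detected = c(0L, 1L, 43L))
  expect_equal(pph_flags(h), c(FALSE, TRUE, TRUE))
})

test_that("monthly metrics reproduce hand-computed arithmetic", {
  fx <- hand_fixture()
  hours <- bin_hourly(filter_trains(fx$trains), fx$effort)
  expect_true(all(hours$complete))
  expect_equal(nrow(hours), 72)
  mm <- monthly_metrics(hours)
  expect_equal(nrow(mm), 1)
  expect_equal(mm$median_pph_per_day, 1)
  expect_equal(mm$total_pph, 2 + 1 + 1)
  expect_equal(mm$max_pph_per_day, 2)
  expect_equal(mm$proportion_days_present, 1)
  expect_equal(mm$n_recording_days, 3)
  # bound: total_pph <= 24 * recording days
  expect_lte(mm$total_pph, 24 * mm$n_recording_days)
})

test_that("monthly metrics handle all-zero months and the 24-PPH/day
           ceiling", {
  eff <- data.frame(site = "A", start = est_time("2015-06-01 00:00:00"),
                    end = est_time("2015-07-01 00:00:00"))
  h <- bin_hourly(hand_fixture()$trains[0, ], eff)
  mm <- monthly_metrics(h)
  expect_equal(mm$median_pph_per_day, 0)
  expect_equal(mm$total_pph, 0)
  expect_equal(mm$max_pph_per_day, 0)
  expect_equal(mm$proportion_days_present, 0)
  expect_equal(mm$n_recording_days, 30)
})

test_that("ISO week assignment matches an independent calendar oracle", {
  expect_equal(iso_week(as.Date("2016-01-01")),
               data.frame(iso_year = 2015L, iso_week = 53L))
  expect_equal(iso_week(as.Date("2015-01-05")),
               data.frame(iso_year = 2015L, iso_week = 2L))
  set.seed(21)
  dates <- as.Date("2010-01-01") + sample.int(4000, 300)
  expect_equal(iso_week(dates), iso_week_oracle(dates))
  # within-week invariance: any Monday maps like the following Sunday
  mondays <- dates[((as.numeric(dates) + 3) %% 7) == 0]
  expect_equal(iso_week(mondays), iso_week(mondays + 6))
})

test_that("weekly occurrence proportions match hand-computed values", {
  fx <- hand_fixture()
  hours <- bin_hourly(filter_trains(fx$trains), fx$effort)
  wk <- weekly_occurrence(hours)
  expect_equal(nrow(wk), 2)
  w9 <- wk[wk$iso_week == 9, ]
  w10 <- wk[wk$iso_week == 10, ]
  expect_equal(w9$n_complete_hours, 24)
  expect_equal(w9$proportion_hours_present, 2 / 24)
  expect_equal(w10$n_complete_hours, 48)
  expect_equal(w10$proportion_hours_present, 2 / 48)
})

test_that("the processing pipeline is invariant to input train order", {
  fx <- hand_fixture()
  tr <- filter_trains(fx$trains)
  set.seed(5)
  tr_shuf <- tr[sample.int(nrow(tr)), , drop = FALSE]
  expect_equal(bin_hourly(tr, fx$effort), bin_hourly(tr_shuf, fx$effort))
})

test_that("summed monthly totals equal the global PPH count on gap-free
           data", {
  cfg <- flat_config(n_days = 90, baseline = 0.7, seed = 14)
  truth <- simulate_occupancy(cfg)
  trains <- filter_trains(simulate_click_trains(truth, cfg))
  hours <- bin_hourly(trains, effort_table(cfg))
  mm <- monthly_metrics(hours, pool_years = FALSE)
  expect_equal(sum(mm$total_pph), sum(pph_flags(hours)))
})

test_that("round trip: binned minutes equal the simulator's realized
           minutes for every complete hour", {
  cfg <- sim_config(seed = 15, site_ids = paste0("site", 1:2),
                    baseline_rate = c(0.1, 0.15),
                    start_date = as.Date("2015-01-01"),
                    end_date = as.Date("2015-06-30"),
                    gap_schedule = list(
                      list(site = "site2", start = as.Date("2015-03-01"),
                           end = as.Date("2015-03-15"))))
  truth <- simulate_occupancy(cfg)
  trains <- filter_trains(simulate_click_trains(truth, cfg))
  hours <- bin_hourly(trains, effort_table(cfg))
  key_h <- paste(hours$site, as.numeric(hours$hour_start))
  key_t <- paste(truth$hourly$site, as.numeric(truth$hourly$hour_start))
  m <- match(key_t, key_h)
  expect_false(any(is.na(m)))
  expect_equal(hours$minutes_detected[m], truth$hourly$minutes)
})
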