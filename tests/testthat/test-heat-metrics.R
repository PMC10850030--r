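make_ts <- function(start, n, step = 3) {
  seq(as.POSIXct(start, tz = "UTC"), by = step * 3600, length.out = n)
}

test_that("noleap normalization removes exactly the Feb 29 steps", {
  # 2000 is a leap year: 2928 3-h steps -> 2920
  leap <- data.frame(timestamp = make_ts("2000-01-01", 2928), val = 1)
  expect_identical(nrow(to_noleap(leap)), 2920L)
  # a non-leap year is unchanged
  plain <- data.frame(timestamp = make_ts("2001-01-01", 2920), val = 1)
  expect_identical(nrow(to_noleap(plain)), 2920L)
  expect_identical(attr(to_noleap(plain), "calendar"), "noleap")
})

test_that("exceedance hours apply the step multiplier", {
  ts <- make_ts("2001-01-01", 2920)
  v <- rep(10, 2920); v[500] <- 30
  expect_equal(as.numeric(exceedance_hours_per_year(v, ts, 26, 3)), 3)
  expect_equal(as.numeric(exceedance_hours_per_year(v, ts, 35, 3)), 0)
  # square wave of 40 exceeding steps = 120 h
  v2 <- rep(10, 2920); v2[1001:1040] <- 27
  expect_equal(as.numeric(exceedance_hours_per_year(v2, ts, 26, 3)), 120)
  expect_error(exceedance_hours_per_year(v, ts, 26, 2), "step_hours")
})

test_that("heat days use the daily-maximum rule with inclusive thresholds", {
  ts <- make_ts("2001-01-01", 8 * 10)
  v <- rep(20, 80)
  v[5] <- 29.0                       # single touching step on day 1
  hd <- heat_days_per_year(v, ts, 29, 3)
  flags <- attr(hd, "flags")
  expect_true(flags$flag[1])
  expect_identical(sum(flags$flag), 1L)
  # hand-built daily maxima
  daily_max <- c(30, 25, 29, 28.9, 35, 20, 31, 22, 29.01, 10)
  v2 <- rep(15, 80)
  v2[seq(1, 80, by = 8) + 3] <- daily_max
  hd2 <- heat_days_per_year(v2, ts, 29, 3)
  expect_identical(attr(hd2, "flags")$flag, daily_max >= 29)
  expect_equal(as.numeric(heat_days_per_year(rep(5, 80), ts, 29, 3)), 0)
})

test_that("partial days are excluded and counted", {
  ts <- make_ts("2001-01-01 06:00:00", 8 * 5)  # starts mid-day
  v <- rep(30, 40)
  hd <- heat_days_per_year(v, ts, 29, 3)
  expect_identical(attr(hd, "excluded_days"), 2L)  # clipped first+last day
  expect_identical(nrow(attr(hd, "flags")), 4L)
})

test_that("mean consecutive-run length follows the stated conventions", {
  expect_equal(mean_consecutive_run(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                                      FALSE), rep(2001, 7)), 2.5)
  expect_equal(mean_consecutive_run(rep(FALSE, 10), rep(2001, 10)), 0)
  expect_equal(mean_consecutive_run(rep(TRUE, 365), rep(2001, 365)), 365)
  # cross-year mean with an empty year: zero vs exclude vs pooled
  flags <- c(TRUE, TRUE, FALSE, rep(FALSE, 3))
  years <- c(rep(2001, 3), rep(2002, 3))
  expect_equal(mean_consecutive_run(flags, years), 1)            # (2+0)/2
  expect_equal(mean_consecutive_run(flags, years, "exclude"), 2)
  expect_equal(mean_consecutive_run(c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
                                    c(2001, 2001, 2001, 2002, 2002, 2002),
                                    pooled = TRUE), 4 / 3)       # runs 1,1,2
})

test_that("stress frequencies are percentages that sum to 100 per stratum", {
  ts <- make_ts("2001-01-01", 2920)
  sf <- stress_frequency(rep(20, 2920), ts)
  full <- sf[sf$stratum == "full-year", ]
  expect_equal(full$pct[full$class == "no thermal stress"], 100)
  expect_equal(sum(full$pct), 100)
  set.seed(1)
  sf2 <- stress_frequency(runif(2920, -10, 50), ts)
  sums <- tapply(sf2$pct, sf2$stratum, sum)
  expect_true(all(abs(sums - 100) < 0.01))
  # hand-built 8-step day: 2 steps slight heat stress, 6 comfortable
  day <- stress_frequency(c(25, 25, rep(20, 6)), make_ts("2001-06-01", 8),
                          strata = "full-year")
  expect_equal(day$pct[day$class == "slight heat stress"], 25)
  expect_equal(day$pct[day$class == "no thermal stress"], 75)
})

test_that("an empty stratum is reported as NA, not zeros", {
  ts <- make_ts("2001-06-01", 8 * 30)  # June only: no DJF steps
  sf <- stress_frequency(rep(20, 240), ts, strata = c("JJA", "DJF"))
  expect_true(all(is.na(sf$pct[sf$stratum == "DJF"])))
  expect_identical(unique(sf$n[sf$stratum == "DJF"]), 0L)
  expect_equal(sum(sf$pct[sf$stratum == "JJA"]), 100)
})

test_that("working-hours filter keeps the closed 09-18 UTC window", {
  yr <- data.frame(timestamp = make_ts("2001-01-01", 2920), v = 1)
  kept <- filter_working_hours(yr)
  expect_identical(nrow(kept), 1460L)   # 4 of 8 daily steps
  hrs <- as.integer(format(kept$timestamp, "%H", tz = "UTC"))
  expect_identical(sort(unique(hrs)), c(9L, 12L, 15L, 18L))
  one_day <- data.frame(timestamp = make_ts("2001-01-01", 8))
  kept_hrs <- format(filter_working_hours(one_day)$timestamp, "%H")
  expect_false("06" %in% kept_hrs)
  expect_true("18" %in% kept_hrs)
})

test_that("metrics match brute-force enumeration on randomized series", {
  set.seed(42)
  for (i in 1:20) {
    n_days <- sample(5:30, 1)
    ts <- make_ts(sprintf("%d-0%d-01", sample(2000:2005, 1), sample(1:9, 1)),
                  8 * n_days)
    v <- round(runif(8 * n_days, 15, 40), 1)
    thr <- sample(c(23, 26, 29, 30, 35), 1)
    yrs <- as.integer(format(ts, "%Y"))
    expect_equal(as.numeric(exceedance_hours_per_year(v, ts, thr, 3)),
                 brute_exceedance_hours(v, yrs, thr, 3))
    hd <- heat_days_per_year(v, ts, thr, 3)
    dates <- as.Date(ts, tz = "UTC")
    bf <- brute_heat_day_flags(v, dates, thr)
    expect_identical(attr(hd, "flags")$flag, unname(bf))
    fl <- attr(hd, "flags")
    expect_equal(mean_consecutive_run(fl$flag, fl$year),
                 brute_mean_run(fl$flag, fl$year))
  }
})

test_that("exceedance statistics are monotone in threshold and shift", {
  set.seed(7)
  ts <- make_ts("2001-01-01", 2920)
  v <- 22 + 8 * sin(seq_len(2920) / 100) + rnorm(2920)
  h <- vapply(c(26, 30, 35), function(t) {
    as.numeric(exceedance_hours_per_year(v, ts, t, 3))
  }, numeric(1))
  expect_true(all(diff(h) <= 0))
  d <- vapply(c(23, 29, 35, 41), function(t) {
    as.numeric(heat_days_per_year(v, ts, t, 3))
  }, numeric(1))
  expect_true(all(diff(d) <= 0))
  h_up <- as.numeric(exceedance_hours_per_year(v + 2, ts, 26, 3))
  expect_gte(h_up, h[1])
})

test_that("heat_metrics_report bundles thresholds per variable", {
  ts <- make_ts("2001-01-01", 2920)
  set.seed(2)
  v <- 24 + 6 * sin(2 * pi * seq_len(2920) / 2920) + rnorm(2920, sd = 2)
  rp <- heat_metrics_report(v, ts, "PET_i", 3, period = "historical")
  expect_identical(rp$thresholds$threshold, c(23, 29, 35, 41))
  expect_true(all(diff(rp$thresholds$hours_per_year) <= 0))
  expect_identical(rp$n_years, 1L)
  expect_false(is.null(rp$stress_freq))
  rp2 <- heat_metrics_report(v, ts, "T_i", 3)
  expect_identical(rp2$thresholds$threshold, c(26, 30, 35))
  expect_null(rp2$stress_freq)
  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(rp, f)
  out <- read.csv(f)
  expect_true(all(c("period", "metric", "value") %in% names(out)))
})
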