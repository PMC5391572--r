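test_that("sleeping period spans first to last 30-min slot with SpO2/HR data", {
  # samples 23:07-06:12 -> slots (anchored 16:00) 23:00-23:30 .. 06:00-06:30
  n <- as.numeric(utc("2016-01-05 06:12:00") - utc("2016-01-04 23:07:00"),
                  units = "secs")
  r <- make_record(list(make_series("spo2", "2016-01-04 23:07:00", n, 96)))
  sp <- detect_sleep_period(r, day_window(r, 1))
  expect_equal(sp$start, utc("2016-01-04 23:00:00"))
  expect_equal(sp$end, utc("2016-01-05 06:30:00"))

  # HR-only data confined to one slot: single-slot period allowed
  r2 <- make_record(list(make_series("heart_rate", "2016-01-05 02:00:00",
                                     1800, 70)))
  sp2 <- detect_sleep_period(r2, day_window(r2, 1))
  expect_equal(sp2$start, utc("2016-01-05 02:00:00"))
  expect_equal(sp2$end, utc("2016-01-05 02:30:00"))

  # activity alone never defines sleep; absence is a valid outcome
  r3 <- make_record(list(make_series("activity", "2016-01-05 02:00:00", 600, 5)))
  expect_null(detect_sleep_period(r3, day_window(r3, 1)))
})

test_that("wear detection splits SpO2 coverage at the gap tolerance", {
  n <- 7 * 3600
  r <- make_record(list(make_series("spo2", "2016-01-04 23:00:00", n, 96)))
  w <- detect_wear(r, day_window(r, 1))
  expect_equal(nrow(w$intervals), 1L)
  expect_equal(w$intervals$start, utc("2016-01-04 23:00:00"))
  expect_equal(w$intervals$end, utc("2016-01-05 05:59:59"))

  # two segments separated by a 2-h gap -> two intervals
  t <- c(utc("2016-01-04 23:00:00") + 0:599,
         utc("2016-01-05 01:10:00") + 0:599)
  r2 <- make_record(list(channel_series("spo2", t, rep(96, length(t)))))
  w2 <- detect_wear(r2, day_window(r2, 1))
  expect_equal(nrow(w2$intervals), 2L)

  # no SpO2 samples -> empty interval list (blue line absent)
  r3 <- make_record(list(make_series("heart_rate", "2016-01-05 02:00:00",
                                     600, 70)))
  expect_equal(nrow(detect_wear(r3, day_window(r3, 1))$intervals), 0L)
})

test_that("block grid is anchored at the day start and sized by block_minutes", {
  day <- make_day()
  g30 <- block_grid(day, 30)
  expect_equal(nrow(g30), 48L)
  expect_equal(g30$start[1], day$start)
  expect_equal(g30$end[1], day$start + 1800)
  expect_equal(g30$end[48], day$end)
  expect_equal(nrow(block_grid(day, 60)), 24L)
  expect_error(block_grid(day, 7), "divide 1440")
})

test_that("activity blocks flag on strict block mean above threshold", {
  day <- make_day()
  cfg <- threshold_config()
  # full block at exactly 12: boundary does not flag
  s12 <- make_series("activity", "2016-01-05 02:00:00", 1800, 12)
  expect_equal(nrow(flag_activity_blocks(s12, day, cfg)), 0L)
  # at 13: flags with the mean as statistic
  s13 <- make_series("activity", "2016-01-05 02:00:00", 1800, 13)
  b <- flag_activity_blocks(s13, day, cfg)
  expect_equal(nrow(b), 1L)
  expect_equal(b$kind, "high")
  expect_equal(b$statistic, 13)
  expect_equal(b$start, utc("2016-01-05 02:00:00"))
  # alternating 0/26 has mean 13: flags
  alt <- channel_series("activity", utc("2016-01-05 02:00:00") + 0:1799,
                        rep(c(0, 26), 900))
  expect_equal(nrow(flag_activity_blocks(alt, day, cfg)), 1L)
})

test_that("range blocks flag any strict threshold crossing with min/max stat", {
  day <- make_day()
  cfg <- threshold_config()
  ok <- make_series("spo2", "2016-01-05 02:00:00", 1800, 95)
  expect_equal(nrow(flag_range_blocks(ok, day, cfg)), 0L)

  v <- rep(95, 1800); v[731] <- 91
  dip <- channel_series("spo2", utc("2016-01-05 02:00:00") + 0:1799, v)
  b <- flag_range_blocks(dip, day, cfg)
  expect_equal(nrow(b), 1L)
  expect_equal(b$kind, "low")
  expect_equal(b$statistic, 91)

  # boundary values (92 / 60 / 100 exactly) never flag
  edge <- channel_series("spo2", utc("2016-01-05 02:00:00") + 0:2, rep(92, 3))
  expect_equal(nrow(flag_range_blocks(edge, day, cfg)), 0L)

  # one HR block containing both 55 and 105 yields a low and a high flag
  hv <- rep(80, 1800); hv[10] <- 55; hv[20] <- 105
  hr <- channel_series("heart_rate", utc("2016-01-05 02:00:00") + 0:1799, hv)
  bh <- flag_range_blocks(hr, day, cfg)
  expect_equal(nrow(bh), 2L)
  expect_setequal(bh$kind, c("low", "high"))
  expect_equal(bh$statistic[bh$kind == "low"], 55)
  expect_equal(bh$statistic[bh$kind == "high"], 105)
})

test_that("min_violation_samples filters single-sample SpO2/HR crossings", {
  day <- make_day()
  v <- rep(95, 1800); v[5] <- 91; v[100:102] <- 91
  s <- channel_series("spo2", utc("2016-01-05 02:00:00") + 0:1799, v)
  expect_equal(nrow(flag_range_blocks(s, day, threshold_config())), 1L)
  expect_equal(nrow(flag_range_blocks(
    s, day, threshold_config(min_violation_samples = 4))), 1L)
  expect_equal(nrow(flag_range_blocks(
    s, day, threshold_config(min_violation_samples = 5))), 0L)
})

test_that("summarize_day restricts blocks to the sleeping period", {
  # three planted desaturations in distinct blocks during sleep
  v <- rep(96, 7 * 3600)
  plant <- function(v, off) { v[off + 1:120] <- 88; v }
  v <- plant(v, 3600); v <- plant(v, 3 * 3600); v <- plant(v, 5 * 3600)
  spo2 <- channel_series("spo2", utc("2016-01-04 23:00:00") + seq_along(v) - 1, v)
  # a daytime activity bout well outside sleep (17:00-17:30, mean 30)
  act <- make_series("activity", "2016-01-04 17:00:00", 1800, 30)
  r <- make_record(list(spo2, act))
  s <- summarize_day(r, 1)
  expect_equal(sum(s$blocks$channel == "spo2"), 3L)
  expect_equal(sum(s$blocks$channel == "activity"), 0L) # not reported
  expect_true(all(s$blocks$start < s$sleep$end & s$blocks$end > s$sleep$start))

  # day with no data -> empty summary, sleep absent
  r0 <- make_record(list(make_series("spo2", "2016-01-04 23:00:00", 10, 96)),
                    n_days = 2L)
  s0 <- summarize_day(r0, 2)
  expect_null(s0$sleep)
  expect_equal(nrow(s0$blocks), 0L)
})

test_that("detection equals the brute-force oracle on random small inputs", {
  for (seed in 1:20) {
    set.seed(seed)
    start <- utc("2016-01-04 22:00:00")
    n <- 4 * 3600
    t <- start + sort(sample(0:(8 * 3600), n))
    spo2 <- channel_series("spo2", t, pmin(100, 96 + rnorm(n, 0, 3)))
    hr <- channel_series("heart_rate", t, pmax(0, 80 + rnorm(n, 0, 18)))
    act <- channel_series("activity", t, abs(rnorm(n, 8, 8)))
    r <- make_record(list(spo2, hr, act))
    day <- day_window(r, 1)
    got <- rbind(flag_range_blocks(spo2, day), flag_range_blocks(hr, day),
                 flag_activity_blocks(act, day))
    want <- oracle_blocks(r, day)
    expect_identical(block_key(got$channel, got$kind, got$start),
                     block_key(want$channel, want$kind, want$start),
                     info = paste("seed", seed))
  }
})

test_that("flags are monotone in the thresholds and order-invariant", {
  set.seed(99)
  start <- utc("2016-01-04 23:00:00")
  n <- 6 * 3600
  t <- start + 0:(n - 1)
  spo2 <- channel_series("spo2", t, pmin(100, 93 + rnorm(n, 0, 2)))
  act <- channel_series("activity", t, abs(rnorm(n, 10, 6)))
  r <- make_record(list(spo2, act))
  day <- day_window(r, 1)

  key <- function(b) block_key(b$channel, b$kind, b$start)
  base_spo2 <- key(flag_range_blocks(spo2, day, threshold_config(spo2_low = 92)))
  for (lo in c(90, 92, 94, 96)) {
    k <- key(flag_range_blocks(spo2, day, threshold_config(spo2_low = lo)))
    if (lo <= 92) expect_true(all(k %in% base_spo2))
    else expect_true(all(base_spo2 %in% k)) # raising spo2_low only adds flags
  }
  base_act <- key(flag_activity_blocks(act, day, threshold_config(activity_high = 12)))
  lower <- key(flag_activity_blocks(act, day, threshold_config(activity_high = 8)))
  expect_true(all(base_act %in% lower)) # lowering activity_high only adds flags

  # shuffling sample order changes nothing
  p <- sample(n)
  spo2_sh <- channel_series("spo2", t[p], spo2$value[p])
  expect_identical(key(flag_range_blocks(spo2_sh, day)), base_spo2)
})

test_that("day_summary_json round-trips the summary content", {
  gen <- generate_record(generator_config(seed = 23, n_nights = 1))
  s <- summarize_day(gen$record, 1)
  j <- jsonlite::fromJSON(day_summary_json(s))
  expect_equal(j$day_index, 1L)
  expect_equal(nrow(j$blocks), nrow(s$blocks))
  expect_equal(j$blocks$statistic, s$blocks$statistic)
  expect_false(is.null(j$sleep$start))
})
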