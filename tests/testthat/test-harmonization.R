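# Epoch aggregation, coverage rule, trailing-window alignment, EMA
# normalization and lock-derived streams.

test_that("epoch_features splits the day into a daily value and four half-open epochs", {
  one_per_hour <- rep(1, 24)
  f <- epoch_features(one_per_hour, "count")
  expect_equal(unname(f), c(24, 6, 6, 6, 6))
  expect_length(f, 5L)

  morning <- rep(0, 24); morning[7:12] <- 2  # hours 6-11, i.e. 6AM-12PM
  f <- epoch_features(morning, "sum")
  expect_equal(unname(f), c(12, 0, 12, 0, 0))

  # a value at exactly 6AM (hour 6) belongs to the second epoch
  at6 <- rep(0, 24); at6[7] <- 5
  expect_equal(unname(epoch_features(at6, "sum"))[2:3], c(0, 5))

  m <- epoch_features(c(rep(NA, 12), rep(2, 12)), "mean")
  expect_equal(unname(m), c(2, NA, NA, 2, 2))
  expect_error(epoch_features(rep(1, 23), "sum"), "24")
})

test_that("19-hour coverage rule keeps exactly the days at or above threshold", {
  days <- data.table::data.table(
    subject = "s1", study = "sl", date = 1:10, hours_with_data = 15:24)
  kept <- filter_low_coverage_days(days, min_hours = 19,
                                   raw_derived = "sl")
  expect_equal(nrow(kept), 6L)
  expect_true(all(kept$hours_with_data >= 19))
  expect_false(18 %in% kept$hours_with_data)
  expect_true(19 %in% kept$hours_with_data)
  # rule only applies to raw-derived studies
  untouched <- filter_low_coverage_days(days, raw_derived = "other")
  expect_equal(nrow(untouched), 10L)
})

test_that("aligned instances average the trailing window and count missing days", {
  sensor <- data.table::rbindlist(lapply(c(4L, 5L, 6L), function(d) {
    toy_sensor_day(date = d, values = list(activity_on_foot = rep(d, 24)))
  }))
  ema <- data.table::data.table(subject = "s1", study = "a", date = 6L,
                                item = "sleep", value = 2, severe = 0L)
  days <- compute_day_features(sensor)
  inst <- build_aligned_instances(days, ema, sleep_fill = FALSE)
  # days 4-6 present: daily sums are 24*d, mean = 24*5
  expect_equal(inst$activity_on_foot.daily, 24 * 5)
  expect_equal(inst$missing_days, 0)
  expect_equal(ncol(inst[, feature_names(), with = FALSE]), 44L)

  # drop day 5: mean of days 4 and 6, one missing day
  inst2 <- build_aligned_instances(days[date != 5L], ema, sleep_fill = FALSE)
  expect_equal(inst2$activity_on_foot.daily, 24 * 5)
  expect_equal(inst2$missing_days, 1)

  # no sensor days at all in window -> instance skipped with warning
  expect_warning(
    empty <- build_aligned_instances(days[date > 90L], ema,
                                     sleep_fill = FALSE),
    "skipped")
  expect_equal(nrow(empty), 0L)
})

test_that("trailing means match a brute-force recomputation on random tables", {
  set.seed(14)
  sensor <- data.table::rbindlist(lapply(1:12, function(d) {
    toy_sensor_day(date = d, values = list(
      activity_on_foot = rpois(24, 3), unlock_duration = runif(24, 0, 30)))
  }))
  keep_days <- sort(sample(1:12, 8))
  days <- compute_day_features(sensor)[date %in% keep_days]
  ema <- data.table::data.table(subject = "s1", study = "a", date = 3:12,
                                item = "sleep", value = 1, severe = 1L)
  suppressWarnings(
    inst <- build_aligned_instances(days, ema, window = 3,
                                    sleep_fill = FALSE))
  for (i in seq_len(nrow(inst))) {
    t <- inst$date[i]
    win <- days[date >= t - 2 & date <= t]
    expect_equal(inst$activity_on_foot.daily[i],
                 mean(win$activity_on_foot.daily))
    expect_equal(inst$unlock_duration.ep3[i], mean(win$unlock_duration.ep3))
    expect_equal(inst$missing_days[i], 3 - nrow(win))
  }
})

test_that("instance table is invariant to input row order", {
  set.seed(9)
  sensor <- data.table::rbindlist(lapply(1:6, function(d) {
    toy_sensor_day(date = d, values = list(conversation_count = rpois(24, 1)))
  }))
  ema <- data.table::data.table(subject = "s1", study = "a", date = c(3L, 6L),
                                item = "sleep", value = c(0, 3),
                                severe = c(1L, 0L))
  base <- build_aligned_instances(compute_day_features(sensor), ema,
                                  sleep_fill = FALSE)
  shuffled <- sensor[sample(.N)]
  again <- build_aligned_instances(compute_day_features(shuffled), ema,
                                   sleep_fill = FALSE)
  expect_equal(base, again)
})

test_that("EMA normalization maps raw scales onto [0,3] with consistent direction", {
  # CrossCheck native scale is the identity
  cc <- mapping_crosscheck("stressed")
  ema <- data.table::data.table(subject = "s1", study = "cc", date = 1L,
                                item = "stressed", raw_value = "2")
  expect_equal(normalize_ema(ema, list(stressed = cc))$value, 2)

  # StudentLife sleep: 1 (very good) -> 3, 4 (very bad) -> 0
  sl <- mapping_studentlife_sleep()
  ema <- data.table::data.table(subject = "s1", study = "sl", date = 1L,
                                item = "sleep", raw_value = c("1", "4"))
  expect_equal(normalize_ema(ema, list(sleep = sl))$value, c(3, 0))

  # StudentLife stress: severity-ordered 5 labels onto the 4-point grid
  st <- mapping_studentlife_stress()
  expect_equal(st$normalized, c(0, 1, 2, 2, 3))
  expect_equal(range(st$normalized), c(0, 3))
  ema <- data.table::data.table(subject = "s1", study = "sl", date = 1L,
                                item = "stress",
                                raw_value = c("Feeling great", "Stressed out"))
  expect_equal(normalize_ema(ema, list(stress = st))$value, c(0, 3))

  # raw value outside the declared domain is a data error naming the item
  bad <- data.table::data.table(subject = "s9", study = "sl", date = 1L,
                                item = "sleep", raw_value = "7")
  expect_error(normalize_ema(bad, list(sleep = sl)), "sleep")
})

test_that("severity labels pick the two severe categories per direction", {
  sleep <- mapping_studentlife_sleep()
  expect_equal(label_severity(c(0, 1, 2, 3), sleep), c(1L, 1L, 0L, 0L))
  stress <- mapping_crosscheck("stressed")
  expect_equal(label_severity(c(0, 1, 2, 3), stress), c(0L, 0L, 1L, 1L))
})

test_that("validation subjects require >= 30 aligned responses", {
  counts <- c(10, 29, 30, 40, 100)
  inst <- data.table::rbindlist(lapply(seq_along(counts), function(i) {
    data.table::data.table(subject = sprintf("s%d", i), item = "sleep",
                           outcome = 0, n = seq_len(counts[i]))
  }))
  expect_equal(select_validation_subjects(inst, "sleep"),
               c("s3", "s4", "s5"))
  expect_equal(select_validation_subjects(inst[0], "sleep"), character(0))
})

test_that("lock intervals yield unlock durations and longest-interval sleep", {
  # locked 11PM day1 to 7AM day2 -> onset 23, wake 31, duration 8
  li <- data.table::data.table(subject = "s1", start = 23, end = 31)
  out <- derive_lock_based_streams(li, n_days = 2)
  sl <- out[variable %in% sleep_variables() & date == 2]
  expect_equal(sl[variable == "sleep_onset"]$value, 23)
  expect_equal(sl[variable == "sleep_wake"]$value, 31)
  expect_equal(sl[variable == "sleep_duration"]$value, 8)
  # hour fully locked -> 0 unlocked minutes; fully unlocked -> 60
  ud <- out[variable == "unlock_duration"]
  expect_equal(ud[date == 2 & hour == 3]$value, 0)
  expect_equal(ud[date == 2 & hour == 15]$value, 60)

  # no locked interval in the night window -> no sleep rows for that day
  li2 <- data.table::data.table(subject = "s1", start = 14, end = 16)
  out2 <- derive_lock_based_streams(li2, n_days = 1)
  expect_equal(nrow(out2[variable %in% sleep_variables()]), 0L)

  # two candidates 10PM-2AM and 3AM-9AM: the 6-hour interval wins
  li3 <- data.table::data.table(subject = "s1", start = c(22, 27),
                                end = c(26, 33))
  sl3 <- derive_lock_based_streams(li3, n_days = 2)[
    variable %in% sleep_variables() & date == 2]
  expect_equal(sl3[variable == "sleep_onset"]$value, 27)
  expect_equal(sl3[variable == "sleep_duration"]$value, 6)

  expect_error(derive_lock_based_streams(
    data.table::data.table(subject = "s1", start = c(1, 3), end = c(4, 6)),
    n_days = 1), "overlap")
})

test_that("sleep fill uses the subject's own mean when a window is empty", {
  sensor <- data.table::rbindlist(lapply(1:6, function(d) {
    toy_sensor_day(date = d, values = list(activity_still = rep(1, 24)))
  }))
  sleep <- data.table::rbindlist(lapply(1:3, function(d) {
    toy_sleep_day(date = d, onset = 22 + d, wake = 30 + d)
  }))
  days <- compute_day_features(rbind(sensor, sleep))
  ema <- data.table::data.table(subject = "s1", study = "a", date = 6L,
                                item = "sleep", value = 2, severe = 0L)
  inst <- build_aligned_instances(days, ema)
  expect_equal(inst$sleep_onset, mean(23:25))
  expect_equal(inst$sleep_duration, 8)
})
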