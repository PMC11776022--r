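test_that("Freedson classification is exact on the band boundaries", {
  expect_identical(as.character(classify_epoch(c(0, 99, 100, 1951, 1952))),
                   c("sedentary", "sedentary", "light", "light", "mvpa"))
  expect_error(classify_epoch(-1), "nonnegative")

  # exhaustive piecewise-constant check over the full observed range
  x <- 0:3000
  got <- as.character(classify_epoch(x))
  want <- ifelse(x < 100, "sedentary", ifelse(x <= 1951, "light", "mvpa"))
  expect_identical(got, want)
})

test_that("wear detection applies the 60-minute zero-run rule", {
  all_zero <- data.frame(minute_of_day = 0:1439, counts = 0L)
  w <- detect_wear(all_zero)
  expect_identical(w$wear_minutes, 0L)
  expect_false(w$valid)

  # a 59-zero run flanked by activity stays wear
  counts <- rep(200L, 1440)
  counts[101:159] <- 0L
  d <- data.frame(minute_of_day = 0:1439, counts = counts)
  expect_identical(detect_wear(d)$wear_minutes, 1440L)

  # 600 active + 840 zero minutes: wear 600, valid
  counts2 <- c(rep(300L, 600), rep(0L, 840))
  d2 <- data.frame(minute_of_day = 0:1439, counts = counts2)
  w2 <- detect_wear(d2)
  expect_identical(w2$wear_minutes, 600L)
  expect_true(w2$valid)

  dup <- data.frame(minute_of_day = c(0, 0, 1), counts = c(1, 2, 3))
  expect_error(detect_wear(dup), "duplicate")
})

test_that("period summaries compose intensities, swim and validity correctly", {
  day <- sedentary_day(wear = 600)
  s <- summarize_period(day, min_days = 1)
  expect_equal(s$st_pct, 100)
  expect_equal(s$mvpa_min_per_day, 0)
  # partition: sedentary + light + mvpa = wear
  expect_equal(s$sed_min_per_day + s$light_min_per_day + s$mvpa_min_per_day,
               s$wear_min_per_day)

  diary <- data.frame(subject_id = "S001", period = "<20w", day = 1L,
                      swim_minutes = 30)
  s2 <- summarize_period(day, diary, min_days = 1)
  expect_equal(s2$mvpa_min_per_day, 30)
  expect_equal(s2$st_pct, 100)   # swimming does not enter wear time

  # two valid days only: flagged invalid at the 3-day floor
  two_days <- rbind(day, transform(day, day = 2L))
  s3 <- summarize_period(two_days, min_days = 3)
  expect_identical(s3$n_valid_days, 2L)
  expect_false(s3$valid)
})

test_that("pregnancy averaging is an unweighted mean over valid periods", {
  mk <- function(period, mvpa, valid = TRUE) {
    data.frame(subject_id = "S001", period = period, n_valid_days = 3L,
               mvpa_min_per_day = mvpa, st_pct = 70, light_min_per_day = 100,
               sed_min_per_day = 400, wear_min_per_day = 600, valid = valid)
  }
  two <- rbind(mk("<20w", 20), mk("24-28w", 40))
  expect_equal(average_pregnancy(two)$mean_mvpa_min_per_day, 30)
  expect_identical(average_pregnancy(two)$n_periods_used, 2L)

  one <- rbind(mk("<20w", 20), mk("24-28w", 40, valid = FALSE))
  expect_error(average_pregnancy(one), "fewer than two valid periods")

  three <- rbind(mk("<20w", 25), mk("24-28w", 25), mk("35-37w", 25))
  expect_equal(average_pregnancy(three)$mean_mvpa_min_per_day, 25)
})

test_that("a zero-MVPA profile yields zero measured MVPA and the stage is deterministic", {
  prof <- activity_profile(mean_mvpa_fraction = 0, mean_sed_fraction = 0.75,
                           mean_light_fraction = 0.25, n_days = 3L)
  acc <- generate_accel_series(prof, n_subjects = 4, seed = 21)
  res <- compute_exposures(acc$counts, acc$swim_diary)
  expect_true(all(res$exposures$mean_mvpa_min_per_day == 0))

  acc2 <- generate_accel_series(prof, n_subjects = 4, seed = 21)
  expect_identical(acc$counts, acc2$counts)
  res2 <- compute_exposures(acc2$counts, acc2$swim_diary)
  expect_identical(res$exposures, res2$exposures)

  expect_error(generate_accel_series(activity_profile(wear_minutes_per_day = 1441),
                                     n_subjects = 2, seed = 1),
               "wear_minutes_per_day")
})

test_that("the calibrated profile reproduces the cohort activity summary", {
  acc <- generate_accel_series(activity_profile(), n_subjects = 30, seed = 13)
  res <- compute_exposures(acc$counts, acc$swim_diary)
  expect_identical(nrow(res$exposures), 30L)
  expect_lt(abs(mean(res$exposures$mean_mvpa_min_per_day) - 39.5) / 39.5, 0.10)
  expect_lt(abs(mean(res$exposures$mean_st_pct) - 72.3) / 72.3, 0.10)
})
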