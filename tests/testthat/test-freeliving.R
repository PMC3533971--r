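test_that("non-wear rule thresholds behave at the boundaries", {
  # exactly 60 zero minutes flanked by activity
  day <- c(rep(500, 10), rep(0, 60), rep(500, 10))
  nw <- detect_non_wear(day)
  expect_equal(nrow(nw), 1L)
  expect_equal(nw$minutes, 60)
  expect_equal(c(nw$start, nw$end), c(10, 70))

  # 59 zeros bounded by activity: below threshold
  expect_equal(nrow(detect_non_wear(c(500, rep(0, 59), 500))), 0L)

  # 30 zeros, 2 interruption minutes, 30 zeros: one 62-min period
  day2 <- c(rep(700, 5), rep(0, 30), 300, 80, rep(0, 30), rep(700, 5))
  nw2 <- detect_non_wear(day2)
  expect_equal(nrow(nw2), 1L)
  expect_equal(nw2$minutes, 62)

  # 3 non-zero minutes spaced so that every possible 60-min window holds all 3
  day3 <- c(rep(0, 30), 5, rep(0, 8), 5, rep(0, 8), 5, rep(0, 30))
  expect_equal(nrow(detect_non_wear(day3)), 0L)
  # oracle agrees on these hand cases
  expect_equal(detect_non_wear(day2), oracle_non_wear(day2))
  expect_equal(detect_non_wear(day3), oracle_non_wear(day3))
})

test_that("MVPA classification respects the >= boundary and wear precedence", {
  counts <- c(685, 684.9, 2000, 0)
  wear <- c(TRUE, TRUE, FALSE, TRUE)
  mv <- classify_mvpa(counts, wear, cut_point = 685)
  expect_equal(mv, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(classify_mvpa(counts, wear, cut_point = 0), "positive")
})

test_that("bout rule thresholds behave at the boundaries", {
  pad <- function(m) c(rep(FALSE, 5), m, rep(FALSE, 5))
  b10 <- detect_bouts(pad(rep(TRUE, 10)))
  expect_equal(b10$minutes, 10)
  expect_equal(nrow(detect_bouts(pad(rep(TRUE, 9)))), 0L)

  # 5 MVPA + 2 drops + 5 MVPA: one 12-min bout
  b12 <- detect_bouts(pad(c(rep(TRUE, 5), rep(FALSE, 2), rep(TRUE, 5))))
  expect_equal(b12$minutes, 12)
  # 3 drops split the window: no bout
  expect_equal(nrow(detect_bouts(pad(c(rep(TRUE, 5), rep(FALSE, 3), rep(TRUE, 5))))), 0L)
})

test_that("scanning detectors agree with the brute-force oracle on random streams", {
  set.seed(2024)
  for (k in 1:150) {
    counts <- random_count_stream(300L)
    expect_identical(detect_non_wear(counts), oracle_non_wear(counts))
    mask <- random_mvpa_mask(300L)
    expect_identical(detect_bouts(mask), oracle_bouts(mask))
  }
})

test_that("day summaries partition wear time and respect the bout-allowance bound", {
  set.seed(77)
  for (k in 1:20) {
    counts <- random_count_stream(sample(200:1440, 1))
    ms <- minute_series(counts, start_minute = 0)
    d <- summarize_day(ms, cut_point = 685)
    nw <- detect_non_wear(counts)
    expect_equal(d$wear_minutes + sum(nw$minutes), length(counts))
    expect_lte(d$mvpa_minutes, d$wear_minutes)
    expect_lte(d$bout_minutes, d$mvpa_minutes + 2 * d$n_bouts)
  }
})

test_that("MVPA and bout minutes are non-increasing in the cut point", {
  set.seed(99)
  counts <- random_count_stream(1000L)
  ms <- minute_series(counts, start_minute = 0)
  cuts <- c(100, 400, 685, 1151, 2000)
  res <- lapply(cuts, function(cp) summarize_day(ms, cut_point = cp))
  mvpa <- vapply(res, `[[`, numeric(1), "mvpa_minutes")
  bouts <- vapply(res, `[[`, numeric(1), "bout_minutes")
  expect_true(all(diff(mvpa) <= 0))
  expect_true(all(diff(bouts) <= 0))
})

test_that("subject summaries enforce the 10-hour day and 5-day rules", {
  # 7 days of constant 1000 counts/min during a 10-h wear window
  one_day <- c(rep(0, 420), rep(1000, 600), rep(0, 420))
  stream <- rep(one_day, 7)
  es <- epoch_series(rep(stream %/% 6, each = 6), epoch_length = 10,
                     start_time = as.POSIXct("2010-06-01 00:00:00", tz = "UTC"))
  res <- summarize_subject(es, cut_point = 685)
  expect_true(res$subject$valid_measurement)
  expect_equal(res$subject$n_valid_days, 7L)
  expect_equal(res$subject$mvpa_per_day, 600)
  expect_equal(res$subject$total_pa, 1000, tolerance = 1e-2)

  # only 4 days with enough wear: measurement invalid, outcomes still averaged
  short <- c(rep(one_day, 4), rep(c(rep(0, 1000), rep(1000, 440)), 3))
  es2 <- epoch_series(rep(short %/% 6, each = 6), epoch_length = 10,
                      start_time = as.POSIXct("2010-06-01 00:00:00", tz = "UTC"))
  res2 <- summarize_subject(es2, cut_point = 685)
  expect_equal(res2$subject$n_valid_days, 4L)
  expect_false(res2$subject$valid_measurement)

  # zero valid days: outcomes flagged missing
  tiny <- epoch_series(rep(c(rep(0, 1200), rep(900, 240)) %/% 6, each = 6) |>
                         rep(2), epoch_length = 10,
                       start_time = as.POSIXct("2010-06-01 00:00:00", tz = "UTC"))
  res3 <- summarize_subject(tiny, cut_point = 685)
  expect_equal(res3$subject$n_valid_days, 0L)
  expect_false(res3$subject$valid_measurement)
  expect_true(is.na(res3$subject$mvpa_per_day))
})

test_that("percent-of-wear and absolute MVPA correlate near 1 on stable wear schedules", {
  set.seed(512)
  fs <- freeliving_scenario(n_days = 5, seed = 512)
  bouts_draw <- lapply(1:10, function(i) sample(0:3, 5, replace = TRUE))
  res <- lapply(1:10, function(i) {
    fs$seed <- 512 + i
    fs$bouts_per_day <- bouts_draw[[i]]
    fl <- generate_freeliving(fs, subject_id = sprintf("P%02d", i))
    summarize_subject(fl$series, cut_point = 685)
  })
  abs_mvpa <- vapply(res, function(r) r$subject$mvpa_per_day, numeric(1))
  pct_mvpa <- vapply(res, function(r) {
    mean(r$days$mvpa_minutes / r$days$wear_minutes)
  }, numeric(1))
  expect_gt(cor(abs_mvpa, pct_mvpa), 0.95)
})
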