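test_that("headerless and ActiLife-style files parse with correct metadata precedence", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0", "120", "0"), f)
  es <- read_epoch_csv(f, epoch_dialect(header = "none", epoch_length = 10))
  expect_s3_class(es, "epoch_series")
  expect_equal(es$counts, c(0, 120, 0))
  expect_equal(es$epoch_length, 10L)

  # ActiLife header: start time and epoch override dialect defaults
  hdr <- c("--- Data File Created By ActiGraph GT1M ActiLife v5.3 ---",
           "Serial Number: XYZ123", "Start Time 08:30:00",
           "Start Date 06/01/2010", "Epoch Period (hh:mm:ss) 00:00:10",
           "Download Time 10:00:00", "Download Date 06/08/2010",
           "Current Memory Address: 0", "Current Battery Voltage: 4.07",
           "--------------------------------------------------")
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(hdr, "15", "250", "0", "42"), g)
  ag <- read_epoch_csv(g, epoch_dialect(header = "actigraph"))
  expect_equal(ag$epoch_length, 10L)
  expect_equal(ag$counts, c(15, 250, 0, 42))
  expect_equal(format(ag$start_time, "%Y-%m-%d %H:%M:%S"), "2010-06-01 08:30:00")

  # conflicting dialect epoch vs header epoch is a configuration error
  expect_error(read_epoch_csv(g, epoch_dialect(header = "actigraph", epoch_length = 60)),
               "configuration error")

  # multi-axis files keep only the vertical (first) column, with a warning
  h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(hdr, "15,3,1", "250,90,2"), h)
  expect_warning(multi <- read_epoch_csv(h, epoch_dialect(header = "actigraph")),
                 "vertical")
  expect_equal(multi$counts, c(15, 250))
})

test_that("malformed, negative and empty inputs raise named parse errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), f)
  expect_error(read_epoch_csv(f, epoch_dialect(epoch_length = 10)), "empty")

  writeLines(c("10", "oops", "20"), f)
  expect_error(read_epoch_csv(f, epoch_dialect(epoch_length = 10)), "line 2")

  writeLines(c("10", "-5"), f)
  expect_error(read_epoch_csv(f, epoch_dialect(epoch_length = 10)), "negative")

  expect_error(epoch_series(c(1, -2)), "non-negative")
  expect_error(epoch_series(1:3, epoch_length = 25), "divide 60")
})

test_that("reintegration sums blocks, drops trailing remainders, and conserves counts", {
  es <- epoch_series(c(10, 20, 30, 40, 50, 60), epoch_length = 10)
  expect_equal(reintegrate(es, 60)$counts, 210)

  es7 <- epoch_series(c(10, 20, 30, 40, 50, 60, 70), epoch_length = 10)
  expect_message(r7 <- reintegrate(es7, 60), "dropped 1")
  expect_equal(r7$counts, 210)

  expect_identical(reintegrate(es, 10), es)
  expect_error(reintegrate(es, 25), "multiple")

  # conservation property over random series with aligned lengths
  set.seed(42)
  for (k in 1:20) {
    blocks <- sample(1:12, 1)
    x <- epoch_series(sample(0:500, blocks * 6, replace = TRUE), epoch_length = 10)
    expect_equal(sum(reintegrate(x, 60)$counts), sum(x$counts))
  }
})

test_that("steady-state counts/min averages a window and respects reintegration", {
  es <- epoch_series(rep(100, 12), epoch_length = 10)
  expect_equal(steady_state_counts(es, 0, 120), 600)

  zeros <- epoch_series(rep(0, 12), epoch_length = 10)
  expect_equal(steady_state_counts(zeros, 0, 120), 0)

  mix <- epoch_series(c(rep(0, 6), rep(120, 6)), epoch_length = 10)
  expect_equal(steady_state_counts(mix, 0, 120), 360)  # 720 counts over 2 min

  expect_error(steady_state_counts(es, 0, 150), "outside")

  # invariance to reintegration on block-aligned windows
  set.seed(1)
  x <- epoch_series(sample(0:300, 36, replace = TRUE), epoch_length = 10)
  expect_equal(steady_state_counts(x, 60, 300),
               steady_state_counts(reintegrate(x, 60), 60, 300))
})

test_that("write/read round trip reproduces a series exactly", {
  set.seed(9)
  es <- epoch_series(sample(0:4000, 360, replace = TRUE), epoch_length = 10,
                     start_time = as.POSIXct("2010-06-01 07:00:00", tz = "UTC"),
                     subject_id = "RT1", placement = "left_hip")
  f <- withr::local_tempfile(fileext = ".csv")
  write_epoch_csv(es, f)
  back <- read_epoch_csv(f, epoch_dialect(header = "tidy"))
  expect_equal(back$counts, es$counts)
  expect_equal(back$epoch_length, es$epoch_length)
  expect_equal(back$subject_id, es$subject_id)
  expect_equal(back$placement, es$placement)
  expect_equal(as.numeric(back$start_time), as.numeric(es$start_time))
})
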