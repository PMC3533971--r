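test_that("MET computation follows the individual and standard conventions", {
  ses <- calibration_session("S1", 3.04,
    data.frame(speed = c(2, 3), vo2 = c(9.12, 3.04), counts_per_min = c(500, 900)))
  ind <- compute_mets(ses, "individual")
  expect_equal(ind$stages$met, c(3.0, 1.0))

  std <- compute_mets(calibration_session("S1", 3.04,
    data.frame(speed = 2, vo2 = 10.5, counts_per_min = 500) |>
      rbind(data.frame(speed = 3, vo2 = 14, counts_per_min = 900))), "standard")
  expect_equal(std$stages$met[1], 3.0)

  expect_error(calibration_session("S1", 0, data.frame(speed = 1:2, vo2 = c(5, 6),
                                                       counts_per_min = c(0, 1))),
               "positive")
})

test_that("individual OLS fit recovers a noiseless line and flags degenerate inputs", {
  ses <- line_session()
  cal <- fit_individual(ses)
  expect_equal(cal$intercept, 2.5276, tolerance = 1e-10)
  expect_equal(cal$slope, 0.000690, tolerance = 1e-10)
  expect_equal(cal$pearson_r, 1, tolerance = 1e-12)
  expect_equal(cal$see, 0, tolerance = 1e-10)

  # constant MET response: slope 0, r reported as 0 with a warning
  flat <- compute_mets(calibration_session("S2", 3,
    data.frame(speed = 2:5, vo2 = rep(9, 4), counts_per_min = c(100, 400, 900, 1300))))
  expect_warning(fcal <- fit_individual(flat), "constant MET")
  expect_equal(fcal$slope, 0, tolerance = 1e-12)
  expect_equal(fcal$pearson_r, 0)

  # insufficient stages and zero count variance are errors
  two <- compute_mets(calibration_session("S3", 3,
    data.frame(speed = 2:3, vo2 = c(6, 9), counts_per_min = c(100, 900))))
  expect_error(fit_individual(two), "at least 3")
  const <- compute_mets(calibration_session("S4", 3,
    data.frame(speed = 2:5, vo2 = c(6, 7, 8, 9), counts_per_min = rep(500, 4))))
  expect_error(fit_individual(const), "singular")
})

test_that("cut-point derivation inverts the fit and floors non-positive crossings", {
  cal <- derive_icp(fit_individual(line_session()))
  expect_equal(cal$icp, (3 - 2.5276) / 0.000690, tolerance = 1e-10)
  expect_false(cal$floor_applied)

  # floor rule: negative and zero raw crossings both become 100 counts/min
  mk <- function(a, b) {
    structure(list(subject_id = "X", intercept = a, slope = b, quad = NA_real_,
                   pearson_r = 1, see = 0, icp = NA_real_, floor_applied = FALSE,
                   model_order = "linear", n_stages = 5L),
              class = "subject_calibration")
  }
  neg <- derive_icp(mk(3.5, 0.001))
  expect_equal(neg$icp, 100)
  expect_true(neg$floor_applied)
  zero <- derive_icp(mk(3.0, 0.001))
  expect_equal(zero$icp, 100)
  expect_true(zero$floor_applied)

  expect_error(derive_icp(mk(2, 0)), "slope is zero")
  expect_warning(derive_icp(mk(4, -0.001)), "implausible")

  # noiseless invertibility across a range of true cut points
  for (true_icp in c(150, 685, 1151, 2500)) {
    b <- 0.0007
    cal <- derive_icp(fit_individual(line_session(intercept = 3 - b * true_icp,
                                                  slope = b)))
    expect_lt(abs(cal$icp - true_icp), 1e-6 * true_icp)
  }
})

test_that("quadratic fits use the smallest positive root for the cut point", {
  counts <- c(200, 600, 1000, 1400, 1800)
  a <- 2.0; b <- 0.002; d <- -3e-7  # concave MET curve
  ses <- compute_mets(calibration_session("Q1", 3.0,
    data.frame(speed = 2:6, vo2 = 3.0 * (a + b * counts + d * counts^2),
               counts_per_min = counts)))
  cal <- derive_icp(fit_individual(ses, order = "quadratic"))
  roots <- sort(Re(polyroot(c(a - 3, b, d))))
  expect_equal(cal$icp, min(roots[roots > 0]), tolerance = 1e-6)
})

test_that("walking speed at a target MET interpolates, extrapolates, and stays monotone", {
  mk <- function(mets, speeds = seq(2, length.out = length(mets))) {
    compute_mets(calibration_session("V", 1,
      data.frame(speed = speeds, vo2 = mets, counts_per_min = seq_along(mets) * 100)))
  }
  expect_equal(speed_at_met(mk(c(2.0, 3.0))), 3.0)
  expect_equal(speed_at_met(mk(c(2.5, 3.5))), 2.5)

  # subject already above 3 METs at the slowest stage: extrapolate below it
  fast <- mk(c(3.2, 4.0, 4.8, 5.6, 6.4))
  expect_equal(speed_at_met(fast), 2 + (3 - 3.2) / 0.8, tolerance = 1e-10)
  expect_lt(speed_at_met(fast), 2)

  # monotone in the target for monotone MET profiles
  prof <- mk(c(2.2, 2.9, 3.6, 4.4, 5.3))
  targets <- seq(2.3, 5.0, by = 0.3)
  speeds <- vapply(targets, function(t) speed_at_met(prof, t), numeric(1))
  expect_true(all(diff(speeds) > 0))
})

test_that("calibration CSV round trip assembles sessions per subject", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- rbind(
    data.frame(subject_id = "A", resting_vo2 = 3.1, speed = 2:4,
               vo2 = c(6, 8, 10), counts_per_min = c(300, 900, 1500)),
    data.frame(subject_id = "B", resting_vo2 = 2.8, speed = 2:4,
               vo2 = c(7, 9, 11), counts_per_min = c(400, 1000, 1600)))
  write.csv(df, f, row.names = FALSE)
  sessions <- read_calibration_csv(f)
  expect_named(sessions, c("A", "B"))
  expect_equal(sessions$B$resting_vo2, 2.8)
  expect_equal(nrow(sessions$A$stages), 3L)
})
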