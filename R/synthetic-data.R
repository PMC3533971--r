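#' Scenario for a synthetic calibration cohort
#'
#' Describes the population from which synthetic treadmill calibration
#' cohorts are drawn. Defaults emulate a severely obese adult cohort:
#' resting VO2 of 3.04 (SD 0.40) ml/kg/min, individual cut points of 1151
#' (SD 685) counts/min truncated below at 100, and treadmill stages at 2-6
#' km/h. Cut-point heterogeneity is coupled to resting VO2 (correlation
#' `icp_rest_cor`) and to the count-per-speed slope, so that resting
#' metabolism and walking economy jointly drive the cut points, as they do
#' physiologically; exact variance decompositions are not hard-coded.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; fully determines the generated cohort.
#' @param resting_vo2_mean,resting_vo2_sd Resting VO2 distribution
#'   (ml/kg/min), truncated below at 1.5.
#' @param icp_mean,icp_sd True individual cut-point distribution
#'   (counts/min), truncated below at `icp_floor`.
#' @param icp_floor Lower truncation for true cut points (counts/min).
#' @param icp_rest_cor Correlation between the resting-VO2 and cut-point
#'   latent draws.
#' @param count_slope_mean,count_slope_sd Counts/min gained per km/h of
#'   treadmill speed (truncated below at 200).
#' @param speed_at_zero Speed (km/h) at which vertical-axis counts
#'   extrapolate to zero (slow-walk threshold of the device).
#' @param met_slope_mean,met_slope_sd Per-subject METs per (counts/min)
#'   slope (truncated below at 2e-4).
#' @param vo2_noise_sd Stage VO2 measurement noise SD (ml/kg/min).
#' @param count_noise_sd Stage counts/min measurement noise SD.
#' @param between_hip_sd Independent per-hip counts/min noise SD used by
#'   [generate_two_hip_pair()]; the default was calibrated by simulation
#'   so that the between-hip cut-point SEM is roughly 288 counts/min, the
#'   magnitude seen when two accelerometers are worn on opposite hips.
#' @param speeds Treadmill stage speeds (km/h), strictly increasing.
#' @param group_model True parameters for [simulate_group_cohort()]:
#'   list with `beta0`, `beta1`, `sigma2_u`, `rho`, `sigma2_e`.
#' @return A list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_subjects = 42L, seed = 20101L,
                            resting_vo2_mean = 3.04, resting_vo2_sd = 0.40,
                            icp_mean = 1151, icp_sd = 685, icp_floor = 100,
                            icp_rest_cor = 0.5,
                            count_slope_mean = 800, count_slope_sd = 150,
                            speed_at_zero = 1.0,
                            met_slope_mean = 0.000690, met_slope_sd = 0.00012,
                            vo2_noise_sd = 0.25, count_noise_sd = 60,
                            between_hip_sd = 480,
                            speeds = c(2, 3, 4, 5, 6),
                            group_model = list(beta0 = 2.5276, beta1 = 0.000690,
                                               sigma2_u = 0.04, rho = 0.5,
                                               sigma2_e = 0.02)) {
  sds <- c(resting_vo2_sd, icp_sd, count_slope_sd, met_slope_sd,
           vo2_noise_sd, count_noise_sd, between_hip_sd)
  if (any(sds < 0)) stop("all scenario SDs must be non-negative", call. = FALSE)
  if (n_subjects < 0) stop("`n_subjects` must be non-negative", call. = FALSE)
  if (icp_floor <= 0) stop("`icp_floor` must be positive", call. = FALSE)
  if (abs(icp_rest_cor) > 1) stop("`icp_rest_cor` must be in [-1, 1]", call. = FALSE)
  if (any(diff(speeds) <= 0)) stop("`speeds` must be strictly increasing", call. = FALSE)
  structure(as.list(environment()), class = "cohort_scenario")
}

# Truncated-normal draw by rejection; errors out rather than looping forever.
.rtrunc_norm <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean < lower) stop("infeasible scenario: degenerate draw below truncation bound",
                           call. = FALSE)
    return(rep(mean, n))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:10000) {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lower) break
      if (try == 10000) stop("infeasible scenario: truncation bound rarely satisfied",
                             call. = FALSE)
    }
    out[i] <- v
  }
  out
}

# Latent per-subject calibration parameters shared by the cohort generators.
.draw_cohort_latents <- function(s) {
  n <- s$n_subjects
  resting <- numeric(n); icp <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:10000) {
      z_rest <- stats::rnorm(1)
      r <- s$resting_vo2_mean + s$resting_vo2_sd * z_rest
      z_icp <- s$icp_rest_cor * z_rest +
        sqrt(1 - s$icp_rest_cor^2) * stats::rnorm(1)
      ic <- s$icp_mean + s$icp_sd * z_icp
      if (r >= 1.5 && ic >= s$icp_floor) break
      if (try == 10000) stop("infeasible scenario: truncation bounds rarely satisfied",
                             call. = FALSE)
    }
    resting[i] <- r; icp[i] <- ic
  }
  count_slope <- .rtrunc_norm(n, s$count_slope_mean, s$count_slope_sd, 200)
  met_slope <- .rtrunc_norm(n, s$met_slope_mean, s$met_slope_sd, 2e-4)
  list(resting_vo2 = resting, icp = icp, count_slope = count_slope,
       met_slope = met_slope)
}

# Assemble one subject's session from latents plus measurement noise.
.build_session <- function(id, s, lat, i, count_noise_sd) {
  counts_true <- pmax(0, lat$count_slope[i] * (s$speeds - s$speed_at_zero))
  a_true <- 3 - lat$met_slope[i] * lat$icp[i]
  met_true <- a_true + lat$met_slope[i] * counts_true
  vo2 <- met_true * lat$resting_vo2[i] +
    if (s$vo2_noise_sd > 0) stats::rnorm(length(met_true), 0, s$vo2_noise_sd) else 0
  vo2 <- pmax(vo2, 0.2)
  counts_obs <- pmax(0, counts_true +
    if (count_noise_sd > 0) stats::rnorm(length(counts_true), 0, count_noise_sd) else 0)
  calibration_session(id, lat$resting_vo2[i],
                      data.frame(speed = s$speeds, vo2 = vo2,
                                 counts_per_min = counts_obs))
}

#' Generate a synthetic treadmill calibration cohort
#'
#' Draws per-subject latent calibration lines (resting VO2, true cut
#' point, count-per-speed slope and MET-per-count slope), constructs stage
#' VO2 and counts/min at the scenario speeds so the implied true cut point
#' equals the drawn one, adds measurement noise, and returns the sessions
#' with a hidden truth table. With all noise SDs zero,
#' [fit_individual()] + [derive_icp()] recover the truth exactly.
#'
#' @param scenario A [cohort_scenario()].
#' @return A list with `sessions` (list of [calibration_session()]) and
#'   `truth` (data frame: `subject_id`, `resting_vo2`, `icp_true`,
#'   `intercept_true`, `slope_true`, `speed_at_3mets_true`).
#' @export
generate_calibration_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  s <- scenario
  if (!is.null(s$seed)) set.seed(s$seed)
  if (s$n_subjects == 0L) {
    return(list(sessions = list(),
                truth = data.frame(subject_id = character(0), resting_vo2 = numeric(0),
                                   icp_true = numeric(0), intercept_true = numeric(0),
                                   slope_true = numeric(0),
                                   speed_at_3mets_true = numeric(0))))
  }
  lat <- .draw_cohort_latents(s)
  ids <- sprintf("S%03d", seq_len(s$n_subjects))
  sessions <- lapply(seq_len(s$n_subjects), function(i) {
    .build_session(ids[i], s, lat, i, s$count_noise_sd)
  })
  truth <- data.frame(
    subject_id = ids,
    resting_vo2 = lat$resting_vo2,
    icp_true = lat$icp,
    intercept_true = 3 - lat$met_slope * lat$icp,
    slope_true = lat$met_slope,
    speed_at_3mets_true = s$speed_at_zero + lat$icp / lat$count_slope,
    stringsAsFactors = FALSE
  )
  list(sessions = sessions, truth = truth)
}

#' Generate paired right/left-hip calibration sessions
#'
#' Duplicates each subject's latent calibration with independent
#' counts/min noise per hip (`between_hip_sd`), emulating two
#' accelerometers worn simultaneously on opposite hips during the same
#' treadmill test: the stage VO2 measurements are shared (one gas
#' analyser), only the count channels differ. With zero between-hip noise
#' both hips yield identical cut points.
#'
#' @param scenario A [cohort_scenario()].
#' @return A list with `right` and `left` (lists of
#'   [calibration_session()]) and `truth` (as in
#'   [generate_calibration_cohort()]).
#' @export
generate_two_hip_pair <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  s <- scenario
  if (!is.null(s$seed)) set.seed(s$seed)
  lat <- .draw_cohort_latents(s)
  ids <- sprintf("S%03d", seq_len(s$n_subjects))
  right <- vector("list", s$n_subjects); left <- vector("list", s$n_subjects)
  for (i in seq_len(s$n_subjects)) {
    counts_true <- pmax(0, lat$count_slope[i] * (s$speeds - s$speed_at_zero))
    a_true <- 3 - lat$met_slope[i] * lat$icp[i]
    met_true <- a_true + lat$met_slope[i] * counts_true
    vo2 <- met_true * lat$resting_vo2[i] +
      if (s$vo2_noise_sd > 0) stats::rnorm(length(met_true), 0, s$vo2_noise_sd) else 0
    vo2 <- pmax(vo2, 0.2)
    noisy_counts <- function() pmax(0, counts_true +
      if (s$between_hip_sd > 0) stats::rnorm(length(counts_true), 0, s$between_hip_sd) else 0)
    right[[i]] <- calibration_session(ids[i], lat$resting_vo2[i],
      data.frame(speed = s$speeds, vo2 = vo2, counts_per_min = noisy_counts()))
    left[[i]] <- calibration_session(ids[i], lat$resting_vo2[i],
      data.frame(speed = s$speeds, vo2 = vo2, counts_per_min = noisy_counts()))
  }
  truth <- data.frame(subject_id = ids, resting_vo2 = lat$resting_vo2,
                      icp_true = lat$icp,
                      intercept_true = 3 - lat$met_slope * lat$icp,
                      slope_true = lat$met_slope,
                      speed_at_3mets_true = s$speed_at_zero + lat$icp / lat$count_slope,
                      stringsAsFactors = FALSE)
  list(right = right, left = left, truth = truth)
}

#' Simulate a cohort directly from the pooled mixed model
#'
#' Generates MET observations from
#' `MET_ij = beta0 + beta1 * counts_ij + u_i + e_ij` with a random
#' intercept and AR(1) within-subject residuals over the stage order, for
#' parameter-recovery studies of [fit_group_model()]. Counts designs are
#' drawn per subject from the scenario's count-per-speed slope; VO2 values
#' are back-constructed so that [compute_mets()] reproduces the simulated
#' METs exactly.
#'
#' @param scenario A [cohort_scenario()]; `group_model` holds the truth.
#' @param seed Optional seed overriding the scenario's.
#' @return A list with `sessions` (METs computable via [compute_mets()])
#'   and `truth` (the `group_model` list).
#' @export
simulate_group_cohort <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  s <- scenario
  gm <- s$group_model
  if (abs(gm$rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed) else if (!is.null(s$seed)) set.seed(s$seed)
  n_st <- length(s$speeds)
  count_slope <- .rtrunc_norm(s$n_subjects, s$count_slope_mean, s$count_slope_sd, 200)
  rest <- s$resting_vo2_mean
  sessions <- lapply(seq_len(s$n_subjects), function(i) {
    counts <- pmax(0, count_slope[i] * (s$speeds - s$speed_at_zero))
    u <- stats::rnorm(1, 0, sqrt(gm$sigma2_u))
    e <- numeric(n_st)
    e[1] <- stats::rnorm(1, 0, sqrt(gm$sigma2_e))
    for (j in seq_len(n_st - 1L)) {
      e[j + 1L] <- gm$rho * e[j] +
        stats::rnorm(1, 0, sqrt(gm$sigma2_e * (1 - gm$rho^2)))
    }
    met <- gm$beta0 + gm$beta1 * counts + u + e
    met <- pmax(met, 0.1)
    compute_mets(calibration_session(sprintf("S%03d", i), rest,
                                     data.frame(speed = s$speeds, vo2 = met * rest,
                                                counts_per_min = counts)))
  })
  list(sessions = sessions, truth = gm)
}

#' Scenario for a synthetic free-living recording
#'
#' Describes a multi-day free-living count stream with planted ground
#' truth: a daily wear window bounded by overnight zero blocks, one
#' planted daytime non-wear block per day, nonzero background (light)
#' activity everywhere else in the wear window, and planted MVPA bouts.
#' Background counts stay below half the smallest candidate cut point and
#' bout intensities at least double the largest, so the truth table is
#' exact for every candidate cut point.
#'
#' @param n_days Number of full recording days.
#' @param seed Integer seed.
#' @param cut_points Candidate cut points (counts/min) the truth table
#'   covers.
#' @param wear_start,wear_end Wear window in minutes of day (0-based,
#'   half-open).
#' @param non_wear_minutes Length of the planted daytime non-wear block
#'   (>= 60; 0 disables it).
#' @param bouts_per_day Integer vector recycled over days: number of
#'   planted MVPA bouts per day.
#' @param bout_minutes Range (min, max) of planted bout window lengths.
#' @param drops_per_bout Range (min, max) of below-cut drop minutes per
#'   bout (0 to 2 keeps every planted window a single qualifying bout).
#' @param background_max_frac Background counts are drawn uniformly on
#'   `[20, background_max_frac * min(cut_points)]`.
#' @param intensity_factor Bout intensity = `intensity_factor *
#'   max(cut_points)` counts/min.
#' @return A list of class `freeliving_scenario`.
#' @export
freeliving_scenario <- function(n_days = 7L, seed = 20102L,
                                cut_points = c(685, 1151),
                                wear_start = 420L, wear_end = 1350L,
                                non_wear_minutes = 75L,
                                bouts_per_day = c(1L, 2L, 3L, 1L, 2L, 1L, 2L),
                                bout_minutes = c(10L, 25L),
                                drops_per_bout = c(0L, 2L),
                                background_max_frac = 0.5,
                                intensity_factor = 2.5) {
  if (n_days < 1L) stop("`n_days` must be at least 1", call. = FALSE)
  if (any(cut_points <= 0)) stop("cut points must be positive", call. = FALSE)
  if (wear_start < 0L || wear_end > 1440L || wear_end <= wear_start) {
    stop("wear window must lie within the day", call. = FALSE)
  }
  if (non_wear_minutes != 0L && non_wear_minutes < 60L) {
    stop("a planted non-wear block must be at least 60 minutes (or 0)", call. = FALSE)
  }
  if (wear_start < 60L || 1440L - wear_end < 60L) {
    stop("overnight blocks must be at least 60 minutes", call. = FALSE)
  }
  if (bout_minutes[1] < 10L) stop("planted bouts must be at least 10 minutes", call. = FALSE)
  if (drops_per_bout[2] > 2L) stop("more than 2 drop minutes would split a bout", call. = FALSE)
  if (background_max_frac <= 0 || background_max_frac > 0.5) {
    stop("`background_max_frac` must be in (0, 0.5]", call. = FALSE)
  }
  if (intensity_factor < 2) stop("`intensity_factor` must be at least 2", call. = FALSE)
  structure(as.list(environment()), class = "freeliving_scenario")
}

# Lay out one planted bout pattern: M-run, drops spread singly, M-run tail.
.bout_pattern <- function(len, drops) {
  if (drops == 0L) return(rep(TRUE, len))
  # place drop minutes as isolated interior minutes
  pat <- rep(TRUE, len)
  gap <- len %/% (drops + 1L)
  pos <- pmin(pmax(seq_len(drops) * gap, 2L), len - 1L)
  pos <- unique(pos)
  pat[pos] <- FALSE
  pat
}

#' Generate a synthetic free-living epoch stream with ground truth
#'
#' Builds a minute-resolution plan per day (wear window, planted non-wear
#' block, background counts, planted MVPA bouts), disaggregates it
#' uniformly to 10-s epochs (counts conserved per minute), and returns the
#' epoch series together with the exact per-day, per-cut-point truth:
#' wear, MVPA and bout minutes implied by the plan. Planted bouts are kept
#' at least 3 background minutes away from each other and from any
#' non-wear boundary so the greedy detectors cannot merge or bridge them.
#'
#' @param scenario A [freeliving_scenario()].
#' @param subject_id Subject identifier for the series.
#' @return A list with `series` (10-s [epoch_series()] starting at
#'   midnight), `truth` (data frame: `day`, `cut_point`, `wear_minutes`,
#'   `mvpa_minutes`, `bout_minutes`, `n_bouts`) and `plan` (per-day minute
#'   vectors, for inspection).
#' @export
generate_freeliving <- function(scenario, subject_id = "F01") {
  stopifnot(inherits(scenario, "freeliving_scenario"))
  s <- scenario
  if (!is.null(s$seed)) set.seed(s$seed)
  bg_max <- floor(s$background_max_frac * min(s$cut_points))
  if (bg_max < 21) {
    stop("scenario validation error: cut points too small for nonzero background activity",
         call. = FALSE)
  }
  intensity <- ceiling(s$intensity_factor * max(s$cut_points))
  n_per_day <- rep_len(as.integer(s$bouts_per_day), s$n_days)

  day_minutes <- vector("list", s$n_days)
  truth_rows <- list()
  for (d in seq_len(s$n_days)) {
    counts <- integer(1440)
    wear_idx <- (s$wear_start + 1L):s$wear_end
    counts[wear_idx] <- sample(20:bg_max, length(wear_idx), replace = TRUE)
    # planted daytime non-wear block, away from the wear-window edges
    nw_start <- NA_integer_
    if (s$non_wear_minutes > 0L) {
      lo <- s$wear_start + 120L
      hi <- s$wear_end - 120L - s$non_wear_minutes
      if (hi <= lo) stop("scenario validation error: wear window too short for the non-wear block",
                         call. = FALSE)
      nw_start <- sample(lo:hi, 1L)
      counts[(nw_start + 1L):(nw_start + s$non_wear_minutes)] <- 0L
    }
    # candidate positions for bouts: inside wear, >= 3 min from zeros/each other
    occupied <- counts == 0L
    bout_specs <- list()
    for (b in seq_len(n_per_day[d])) {
      len <- sample(s$bout_minutes[1]:s$bout_minutes[2], 1L)
      drops <- sample(s$drops_per_bout[1]:s$drops_per_bout[2], 1L)
      placed <- FALSE
      for (try in 1:500) {
        st0 <- sample((s$wear_start + 4L):(s$wear_end - len - 4L), 1L)
        span <- (st0 - 3L):(st0 + len + 3L)  # bout plus 3-min guard bands
        if (any(span < 1L) || any(span > 1440L) || any(occupied[span])) next
        pat <- .bout_pattern(len, drops)
        counts[(st0 + 1L):(st0 + len)][pat] <- intensity
        # drop minutes keep their background level (below every cut point)
        occupied[span] <- TRUE
        bout_specs[[length(bout_specs) + 1L]] <- list(start = st0, len = len,
                                                      pattern = pat)
        placed <- TRUE
        break
      }
      if (!placed) stop("scenario validation error: could not place a planted bout without overlap",
                        call. = FALSE)
    }
    # drop minutes keep background counts (> 0), so wear is simply the
    # nonzero minutes of the plan
    wear_true <- sum(counts > 0L)
    mvpa_true <- sum(vapply(bout_specs, function(bs) sum(bs$pattern), integer(1)))
    bout_true <- sum(vapply(bout_specs, function(bs) {
      if (bs$len >= 10L) bs$len else 0L
    }, integer(1)))
    n_bouts_true <- sum(vapply(bout_specs, function(bs) bs$len >= 10L, logical(1)))
    day_minutes[[d]] <- counts
    for (cp in s$cut_points) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        day = as.Date("2010-06-01") + d - 1L, cut_point = cp,
        wear_minutes = wear_true, mvpa_minutes = mvpa_true,
        bout_minutes = bout_true, n_bouts = n_bouts_true)
    }
  }
  minute_stream <- unlist(day_minutes)
  # disaggregate each minute evenly over six 10-s epochs, conserving counts
  base <- rep(minute_stream %/% 6L, each = 6L)
  rem <- minute_stream %% 6L
  bump <- unlist(lapply(rem, function(r) c(rep(1L, r), rep(0L, 6L - r))))
  epochs <- base + bump
  series <- epoch_series(epochs, epoch_length = 10,
                         start_time = as.POSIXct("2010-06-01 00:00:00", tz = "UTC"),
                         subject_id = subject_id)
  list(series = series, truth = do.call(rbind, truth_rows), plan = day_minutes)
}
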