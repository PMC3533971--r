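#' Minute-level count series for one calendar day
#'
#' @param counts_per_min Numeric vector of non-negative counts/min, one per
#'   recorded minute (at most 1440).
#' @param day Calendar date (`Date`).
#' @param subject_id Subject identifier.
#' @param start_minute 0-based minute-of-day of the first element (partial
#'   first days of a recording need not start at midnight).
#' @return An object of class `minute_series`.
#' @export
minute_series <- function(counts_per_min, day = as.Date("2010-01-01"),
                          subject_id = "S01", start_minute = 0L) {
  if (!is.numeric(counts_per_min) || length(counts_per_min) == 0L) {
    stop("`counts_per_min` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(counts_per_min < 0) || anyNA(counts_per_min)) {
    stop("counts/min must be non-negative and non-missing", call. = FALSE)
  }
  start_minute <- as.integer(start_minute)
  if (start_minute < 0L || start_minute + length(counts_per_min) > 1440L) {
    stop("minute series must fit within one calendar day (1440 minutes)", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), day = as.Date(day),
                 start_minute = start_minute,
                 counts_per_min = as.numeric(counts_per_min)),
            class = "minute_series")
}

#' Detect non-wear periods in a day of minute counts
#'
#' A non-wear period is a maximal run of at least `window` minutes (default
#' 60) containing at most `allowance` minutes (default 2) with non-zero
#' counts. The scan is greedy left-to-right: a candidate period opens at a
#' zero-count minute, extends until including the next minute would exceed
#' the interruption allowance, is trimmed of trailing non-zero minutes, and
#' is emitted if it reaches the minimum length; scanning resumes after an
#' emitted period, so periods never overlap. Interruption minutes may have
#' any count magnitude (no spike threshold is applied, unlike
#' Troiano-style 100-count rules).
#'
#' @param x A `minute_series` or a numeric vector of per-minute counts.
#' @param window Minimum non-wear duration in minutes.
#' @param allowance Maximum number of non-zero interruption minutes.
#' @return A data frame with columns `start`, `end` (0-based, half-open
#'   minute indices into `x`) and `minutes`; zero rows if the day is all
#'   wear.
#' @examples
#' detect_non_wear(c(rep(0, 30), 50, 80, rep(0, 30), rep(500, 10)))
#' @export
detect_non_wear <- function(x, window = 60L, allowance = 2L) {
  counts <- if (inherits(x, "minute_series")) x$counts_per_min else as.numeric(x)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  nz <- counts > 0
  n <- length(counts)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (nz[i]) { i <- i + 1L; next }
    j <- i; interruptions <- 0L
    while (j <= n) {
      if (nz[j]) {
        if (interruptions == allowance) break
        interruptions <- interruptions + 1L
      }
      j <- j + 1L
    }
    end <- j - 1L
    while (end >= i && nz[end]) end <- end - 1L
    if (end - i + 1L >= window) {
      starts <- c(starts, i - 1L); ends <- c(ends, end)
      i <- end + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, end = ends, minutes = ends - starts)
}

#' Wear mask from non-wear intervals
#'
#' @param n_minutes Number of recorded minutes.
#' @param non_wear Interval data frame from [detect_non_wear()].
#' @return Logical vector, `TRUE` for worn minutes.
#' @export
wear_mask <- function(n_minutes, non_wear) {
  mask <- rep(TRUE, n_minutes)
  if (nrow(non_wear) > 0L) {
    for (k in seq_len(nrow(non_wear))) {
      mask[(non_wear$start[k] + 1L):non_wear$end[k]] <- FALSE
    }
  }
  mask
}

#' Classify minutes as MVPA under a cut point
#'
#' A worn minute is moderate-to-vigorous physical activity (MVPA) when its
#' counts/min reach the cut point (`>=` convention: the cut point itself
#' attains the target MET level, being the exact solution of the
#' calibration line at 3 METs). Non-wear minutes are never MVPA.
#'
#' @param x A `minute_series` or numeric vector of per-minute counts.
#' @param wear Logical wear mask (same length); `NULL` runs
#'   [detect_non_wear()] first.
#' @param cut_point Cut point in counts/min (> 0).
#' @return Logical MVPA mask.
#' @export
classify_mvpa <- function(x, wear = NULL, cut_point) {
  counts <- if (inherits(x, "minute_series")) x$counts_per_min else as.numeric(x)
  if (!is.numeric(cut_point) || length(cut_point) != 1L || cut_point <= 0) {
    stop("`cut_point` must be a single positive counts/min value", call. = FALSE)
  }
  if (is.null(wear)) wear <- wear_mask(length(counts), detect_non_wear(counts))
  if (length(wear) != length(counts)) stop("wear mask length mismatch", call. = FALSE)
  wear & counts >= cut_point
}

#' Detect bouts of MVPA
#'
#' A bout is a window of at least `min_duration` minutes (default 10) that
#' starts and ends on an MVPA minute and contains at most `max_drop`
#' minutes (default 2, total per bout) below the cut point. The scan is
#' greedy left-to-right: a candidate opens at the first unconsumed MVPA
#' minute, extends until including the next minute would exceed the drop
#' allowance, is trimmed of trailing non-MVPA minutes, and is emitted if
#' long enough; scanning resumes after an emitted bout. Non-wear minutes
#' count as drop minutes, so a bout can bridge at most `max_drop` minutes
#' of non-wear. Bout minutes include the allowed drop minutes.
#'
#' @param mvpa Logical MVPA mask (from [classify_mvpa()]).
#' @param min_duration Minimum bout length in minutes.
#' @param max_drop Maximum below-cut-point minutes per bout.
#' @return Data frame with columns `start`, `end` (0-based half-open) and
#'   `minutes`.
#' @export
detect_bouts <- function(mvpa, min_duration = 10L, max_drop = 2L) {
  mvpa <- as.logical(mvpa)
  if (anyNA(mvpa)) stop("MVPA mask must not contain NA", call. = FALSE)
  n <- length(mvpa)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (!mvpa[i]) { i <- i + 1L; next }
    j <- i; drops <- 0L
    while (j <= n) {
      if (!mvpa[j]) {
        if (drops == max_drop) break
        drops <- drops + 1L
      }
      j <- j + 1L
    }
    end <- j - 1L
    while (end >= i && !mvpa[end]) end <- end - 1L
    if (end - i + 1L >= min_duration) {
      starts <- c(starts, i - 1L); ends <- c(ends, end)
      i <- end + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, end = ends, minutes = ends - starts)
}

#' Score one day of minute counts
#'
#' Runs non-wear detection, MVPA classification and bout detection on one
#' day and tallies wear minutes, MVPA minutes and bouted MVPA minutes. A
#' day is valid when it has at least `min_wear` minutes (default 600, i.e.
#' 10 h) of wear.
#'
#' @param ms A [minute_series()].
#' @param cut_point Cut point in counts/min.
#' @param min_wear Minimum wear minutes for a valid day.
#' @param nw_window,nw_allowance Non-wear rule parameters
#'   ([detect_non_wear()]).
#' @param bout_min,bout_drop Bout rule parameters ([detect_bouts()]).
#' @return A one-row data frame: `subject_id`, `day`, `recorded_minutes`,
#'   `wear_minutes`, `valid`, `mvpa_minutes`, `bout_minutes`, `n_bouts`,
#'   `wear_counts` (total counts over worn minutes).
#' @export
summarize_day <- function(ms, cut_point, min_wear = 600L,
                          nw_window = 60L, nw_allowance = 2L,
                          bout_min = 10L, bout_drop = 2L) {
  stopifnot(inherits(ms, "minute_series"))
  counts <- ms$counts_per_min
  nw <- detect_non_wear(counts, window = nw_window, allowance = nw_allowance)
  wear <- wear_mask(length(counts), nw)
  mvpa <- classify_mvpa(counts, wear, cut_point)
  bouts <- detect_bouts(mvpa, min_duration = bout_min, max_drop = bout_drop)
  wear_min <- sum(wear)
  data.frame(
    subject_id = ms$subject_id, day = ms$day,
    recorded_minutes = length(counts),
    wear_minutes = wear_min, valid = wear_min >= min_wear,
    mvpa_minutes = sum(mvpa),
    bout_minutes = sum(bouts$minutes), n_bouts = nrow(bouts),
    wear_counts = sum(counts[wear]),
    stringsAsFactors = FALSE
  )
}

#' Split an epoch series into per-day minute series
#'
#' Reintegrates to 60-s epochs (dropping any trailing partial minute) and
#' splits the minute stream at calendar midnights. The series must start on
#' a whole minute.
#'
#' @param series An [epoch_series()].
#' @return A list of [minute_series()], one per calendar day, in order.
#' @export
split_days <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  if (as.numeric(series$start_time) %% 60 != 0) {
    stop("series must start on a whole minute for day-level scoring", call. = FALSE)
  }
  mins <- if (series$epoch_length == 60L) series else
    suppressMessages(reintegrate(series, 60L))
  ts <- epoch_timestamps(mins)
  day <- as.Date(ts, tz = "UTC")
  minute_of_day <- (as.numeric(ts) %/% 60) %% 1440
  idx <- split(seq_along(day), day)
  lapply(names(idx), function(d) {
    i <- idx[[d]]
    minute_series(mins$counts[i], day = as.Date(d), subject_id = mins$subject_id,
                  start_minute = minute_of_day[i[1]])
  })
}

#' Score a free-living recording for one subject
#'
#' Reintegrates the epoch stream to minutes, splits it into calendar days,
#' screens each day for wear time, and averages MVPA and bouted-MVPA
#' minutes over valid days. A measurement is valid when it has at least
#' `min_days` valid days (default 5, each with >= 10 h wear). Total PA
#' level is the mean counts/min over the wear time of valid days.
#'
#' @param series An [epoch_series()] covering one or more days.
#' @param cut_point Cut point in counts/min.
#' @param min_days Minimum number of valid days for a valid measurement.
#' @inheritParams summarize_day
#' @return A list with `subject` (one-row data frame: `subject_id`,
#'   `n_days`, `n_valid_days`, `valid_measurement`, `mvpa_per_day`,
#'   `bouts_per_day`, `total_pa`) and `days` (per-day data frame from
#'   [summarize_day()]).
#' @export
summarize_subject <- function(series, cut_point, min_days = 5L, min_wear = 600L,
                              nw_window = 60L, nw_allowance = 2L,
                              bout_min = 10L, bout_drop = 2L) {
  days <- split_days(series)
  per_day <- do.call(rbind, lapply(days, summarize_day, cut_point = cut_point,
                                   min_wear = min_wear, nw_window = nw_window,
                                   nw_allowance = nw_allowance,
                                   bout_min = bout_min, bout_drop = bout_drop))
  valid <- per_day[per_day$valid, , drop = FALSE]
  n_valid <- nrow(valid)
  subject <- data.frame(
    subject_id = series$subject_id,
    n_days = nrow(per_day),
    n_valid_days = n_valid,
    valid_measurement = n_valid >= min_days,
    mvpa_per_day = if (n_valid > 0L) mean(valid$mvpa_minutes) else NA_real_,
    bouts_per_day = if (n_valid > 0L) mean(valid$bout_minutes) else NA_real_,
    total_pa = if (n_valid > 0L && sum(valid$wear_minutes) > 0) {
      sum(valid$wear_counts) / sum(valid$wear_minutes)
    } else NA_real_,
    stringsAsFactors = FALSE
  )
  list(subject = subject, days = per_day)
}
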