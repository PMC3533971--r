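#' Treadmill calibration session for one subject
#'
#' Holds a subject's resting oxygen uptake and the steady-state measurements
#' from an incremental treadmill walking protocol (typically 2, 3, 4, 5 and
#' 6 km/h): per-stage steady-state VO2 and mean accelerometer counts/min.
#' MET values are filled in by [compute_mets()].
#'
#' @param subject_id Subject identifier.
#' @param resting_vo2 Resting oxygen uptake in ml/kg/min (> 0).
#' @param stages A data frame with columns `speed` (km/h, strictly
#'   increasing), `vo2` (ml/kg/min, > 0) and `counts_per_min` (>= 0); at
#'   least two stages.
#' @return An object of class `calibration_session`.
#' @examples
#' ses <- calibration_session("S01", resting_vo2 = 3.0,
#'   stages = data.frame(speed = 2:6, vo2 = c(7, 8.5, 10, 12, 14.5),
#'                       counts_per_min = c(300, 900, 1600, 2400, 3300)))
#' @export
calibration_session <- function(subject_id, resting_vo2, stages) {
  if (!is.numeric(resting_vo2) || length(resting_vo2) != 1L || is.na(resting_vo2) ||
      resting_vo2 <= 0) {
    stop("`resting_vo2` must be a single positive value (ml/kg/min)", call. = FALSE)
  }
  if (!is.data.frame(stages) || !all(c("speed", "vo2", "counts_per_min") %in% names(stages))) {
    stop("`stages` must be a data frame with columns speed, vo2, counts_per_min",
         call. = FALSE)
  }
  if (nrow(stages) < 2L) stop("at least 2 treadmill stages are required", call. = FALSE)
  if (any(diff(stages$speed) <= 0)) stop("stage speeds must be strictly increasing", call. = FALSE)
  if (any(stages$vo2 <= 0)) stop("stage VO2 values must be positive", call. = FALSE)
  if (any(stages$counts_per_min < 0)) stop("stage counts/min must be non-negative", call. = FALSE)
  stages <- stages[, c("speed", "vo2", "counts_per_min")]
  stages$met <- rep(NA_real_, nrow(stages))
  structure(list(subject_id = as.character(subject_id),
                 resting_vo2 = resting_vo2, stages = stages),
            class = "calibration_session")
}

#' @export
print.calibration_session <- function(x, ...) {
  cat(sprintf("<calibration_session> subject %s, resting VO2 %.2f ml/kg/min, %d stages\n",
              x$subject_id, x$resting_vo2, nrow(x$stages)))
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Express stage workloads as MET values
#'
#' In `"individual"` mode each stage's steady-state VO2 is divided by the
#' subject's own resting VO2, giving individually adjusted METs (the
#' original definition of 1 MET as resting metabolic rate). In
#' `"standard"` mode the conventional reference of 3.5 ml/kg/min is used
#' instead.
#'
#' @param session A [calibration_session()].
#' @param mode `"individual"` (default) or `"standard"`.
#' @return The session with the `met` column of `stages` filled in.
#' @export
compute_mets <- function(session, mode = c("individual", "standard")) {
  stopifnot(inherits(session, "calibration_session"))
  mode <- match.arg(mode)
  denom <- if (mode == "individual") session$resting_vo2 else 3.5
  session$stages$met <- session$stages$vo2 / denom
  session$met_mode <- mode
  session
}

#' Fit a subject's count-to-MET regression
#'
#' Ordinary least-squares fit of MET values on counts/min across the
#' treadmill stages. The linear fit reports the Pearson correlation between
#' METs and counts and the standard error of the estimate
#' (SEE = sqrt(RSS / (n - p))). A quadratic fit (counts + counts^2) is
#' available for subjects with visible curvature, but the linear model is
#' the default: with only five stages a quadratic is prone to overfitting.
#'
#' @param session A [calibration_session()] with METs computed.
#' @param order `"linear"` (default) or `"quadratic"`.
#' @return An object of class `subject_calibration` with elements
#'   `subject_id`, `intercept` (METs), `slope` (METs per count/min),
#'   `quad` (METs per (count/min)^2, quadratic only), `pearson_r`, `see`,
#'   `icp` (NA until [derive_icp()]), `floor_applied`, `model_order`,
#'   `n_stages`.
#' @export
fit_individual <- function(session, order = c("linear", "quadratic")) {
  stopifnot(inherits(session, "calibration_session"))
  order <- match.arg(order)
  st <- session$stages
  if (anyNA(st$met)) stop("METs not computed; call compute_mets() first", call. = FALSE)
  n <- nrow(st)
  p <- if (order == "linear") 2L else 3L
  if (n < p + 1L) {
    stop(sprintf("%s fit needs at least %d stages, got %d", order, p + 1L, n),
         call. = FALSE)
  }
  if (stats::var(st$counts_per_min) == 0) {
    stop("singular fit: counts/min are constant across stages", call. = FALSE)
  }
  fml <- if (order == "linear") met ~ counts_per_min else
    met ~ counts_per_min + I(counts_per_min^2)
  fit <- stats::lm(fml, data = st)
  cf <- unname(stats::coef(fit))
  see <- sqrt(sum(stats::residuals(fit)^2) / (n - p))
  if (stats::var(st$met) == 0) {
    warning("constant MET response across stages; Pearson r reported as 0",
            call. = FALSE)
    r <- 0
  } else {
    r <- stats::cor(st$met, st$counts_per_min)
  }
  structure(list(subject_id = session$subject_id,
                 intercept = cf[1], slope = cf[2],
                 quad = if (order == "quadratic") cf[3] else NA_real_,
                 pearson_r = r, see = see,
                 icp = NA_real_, floor_applied = FALSE,
                 model_order = order, n_stages = n),
            class = "subject_calibration")
}

#' @export
print.subject_calibration <- function(x, ...) {
  cat(sprintf("<subject_calibration> subject %s (%s fit, %d stages)\n",
              x$subject_id, x$model_order, x$n_stages))
  cat(sprintf("  MET = %.4f + %.6f * counts/min%s\n", x$intercept, x$slope,
              if (!is.na(x$quad)) sprintf(" + %.3e * (counts/min)^2", x$quad) else ""))
  cat(sprintf("  r = %.3f, SEE = %.3f METs\n", x$pearson_r, x$see))
  if (!is.na(x$icp)) {
    cat(sprintf("  ICP = %.1f counts/min%s\n", x$icp,
                if (x$floor_applied) " (floored at 100)" else ""))
  }
  invisible(x)
}

#' Derive the individual cut point (ICP)
#'
#' Solves the fitted count-to-MET regression for the counts/min at which it
#' crosses the target MET level (3 METs for the moderate-intensity
#' threshold). Raw cut points at or below zero are replaced with a floor of
#' 100 counts/min: a non-positive cut point would classify all wear time as
#' MVPA, which is physiologically meaningless.
#'
#' @param cal A `subject_calibration` from [fit_individual()].
#' @param target_met Target MET level (default 3).
#' @return The calibration with `icp` (counts/min) and `floor_applied` set.
#' @examples
#' ses <- calibration_session("S01", 3.0,
#'   data.frame(speed = 2:6, vo2 = c(7, 8.5, 10, 12, 14.5),
#'              counts_per_min = c(300, 900, 1600, 2400, 3300)))
#' cal <- derive_icp(fit_individual(compute_mets(ses)))
#' cal$icp
#' @export
derive_icp <- function(cal, target_met = 3) {
  stopifnot(inherits(cal, "subject_calibration"))
  a <- cal$intercept; b <- cal$slope
  if (cal$model_order == "quadratic") {
    d <- cal$quad
    roots <- polyroot(c(a - target_met, b, d))
    real <- Re(roots)[abs(Im(roots)) < 1e-8]
    pos <- sort(real[real > 0])
    if (length(pos) == 0L) {
      if (length(real) == 0L) {
        stop("no real crossing of the target MET level for quadratic fit", call. = FALSE)
      }
      cal$icp <- 100; cal$floor_applied <- TRUE
      return(cal)
    }
    cal$icp <- pos[1]; cal$floor_applied <- FALSE
    return(cal)
  }
  if (b == 0) stop("slope is zero: regression never crosses the target MET level",
                   call. = FALSE)
  if (b < 0) warning("negative count-to-MET slope is physiologically implausible",
                     call. = FALSE)
  icp <- (target_met - a) / b
  # boundary crossings at 0 are floored; the tolerance absorbs least-squares
  # round-off (negligible against the 100 counts/min floor)
  if (icp <= 1e-9) {
    cal$icp <- 100
    cal$floor_applied <- TRUE
  } else {
    cal$icp <- icp
    cal$floor_applied <- FALSE
  }
  cal
}

#' Walking speed at a target MET level
#'
#' Interpolates the treadmill speed at which the subject reaches the target
#' MET level, using piecewise-linear interpolation of speed against METs
#' over the stages. Subjects who already exceed the target at the slowest
#' stage are extrapolated below it along the line through the first two
#' stages (many severely obese subjects exceed 3 METs at 2 km/h); the
#' result is clamped at 0 km/h.
#'
#' @param session A [calibration_session()] with METs computed.
#' @param target_met Target MET level (default 3).
#' @return Speed in km/h.
#' @export
speed_at_met <- function(session, target_met = 3) {
  stopifnot(inherits(session, "calibration_session"))
  st <- session$stages
  if (anyNA(st$met)) stop("METs not computed; call compute_mets() first", call. = FALSE)
  mets <- st$met; speeds <- st$speed
  n <- length(mets)
  if (n < 2L) stop("at least 2 stages required", call. = FALSE)
  if (any(diff(mets) <= 0)) {
    crossings <- which(diff(mets >= target_met) != 0 | (mets >= target_met)[-n] &
                         (mets >= target_met)[-1])
    warning("non-monotone MET profile; using the first crossing", call. = FALSE)
  }
  if (target_met < mets[1]) {
    # extrapolate below the first stage along the first two stages
    slope <- (speeds[2] - speeds[1]) / (mets[2] - mets[1])
    return(max(0, speeds[1] + slope * (target_met - mets[1])))
  }
  # first interval whose upper node reaches the target
  for (i in seq_len(n - 1L)) {
    lo <- mets[i]; hi <- mets[i + 1L]
    if ((lo <= target_met && target_met <= hi) || (hi <= target_met && target_met <= lo)) {
      if (hi == lo) return(speeds[i])
      w <- (target_met - lo) / (hi - lo)
      return(max(0, speeds[i] + w * (speeds[i + 1L] - speeds[i])))
    }
  }
  # target above all stages: extrapolate along the last two stages
  slope <- (speeds[n] - speeds[n - 1L]) / (mets[n] - mets[n - 1L])
  max(0, speeds[n] + slope * (target_met - mets[n]))
}

#' Tabulate per-subject calibrations
#'
#' @param cals A list of `subject_calibration` objects.
#' @return A data frame with one row per subject: `subject_id`, `intercept`,
#'   `slope`, `pearson_r`, `see`, `icp`, `floor_applied`, `model_order`.
#' @export
calibration_table <- function(cals) {
  stopifnot(length(cals) > 0L, all(vapply(cals, inherits, logical(1), "subject_calibration")))
  do.call(rbind, lapply(cals, function(x) {
    data.frame(subject_id = x$subject_id, intercept = x$intercept,
               slope = x$slope, pearson_r = x$pearson_r, see = x$see,
               icp = x$icp, floor_applied = x$floor_applied,
               model_order = x$model_order, stringsAsFactors = FALSE)
  }))
}

#' Read calibration sessions from a tidy CSV
#'
#' Expects columns `subject_id, resting_vo2, speed, vo2, counts_per_min`,
#' one row per treadmill stage.
#'
#' @param path CSV path.
#' @return A named list of [calibration_session()] objects.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "resting_vo2", "speed", "vo2", "counts_per_min")
  if (!all(need %in% names(df))) {
    stop(sprintf("calibration file must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  split_df <- split(df, df$subject_id)
  sessions <- lapply(split_df, function(d) {
    rv <- unique(d$resting_vo2)
    if (length(rv) != 1L) {
      stop(sprintf("subject %s has inconsistent resting_vo2 values", d$subject_id[1]),
           call. = FALSE)
    }
    if (is.na(rv)) {
      stop(sprintf("subject %s is missing resting_vo2", d$subject_id[1]), call. = FALSE)
    }
    d <- d[order(d$speed), ]
    calibration_session(d$subject_id[1], rv,
                        d[, c("speed", "vo2", "counts_per_min")])
  })
  sessions[order(names(sessions))]
}
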