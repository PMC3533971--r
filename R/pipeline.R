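#' Pipeline run configuration
#'
#' Assembles a full run configuration from a YAML file and/or explicit
#' overrides. Every analysis threshold is a config key defaulting to the
#' standard protocol values: a 3-MET target, 60-min non-wear window with a
#' 2-min interruption allowance, 600-min valid-day rule, 5-day valid
#' measurement rule, 10-min bouts with a 2-min drop allowance, and a
#' 100-count cut-point floor (applied inside [derive_icp()]). The full
#' configuration is echoed into a JSON manifest next to every output so a
#' run can be reproduced exactly.
#'
#' @param path Optional YAML file with config keys.
#' @param ... Named overrides applied after the file.
#' @return A list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    calibration_csv = NULL, epoch_files = NULL, cut_point_csv = NULL,
    outcomes_csv = NULL, output_dir = "accelcal-output",
    dialect_header = "none", epoch_length = 10, analysis_epoch = 60,
    met_mode = "individual", model_order = "linear", target_met = 3,
    min_wear = 600, min_days = 5, nw_window = 60, nw_allowance = 2,
    bout_min = 10, bout_drop = 2, guideline_minutes = 30,
    ba_center = "median", skip_bad = FALSE, seed = 1L,
    n_subjects = 42, n_days = 7
  )
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
                          call. = FALSE)
    cfg[names(overrides)] <- overrides
  }
  structure(cfg, class = "run_config")
}

.write_manifest <- function(cfg, outdir, step) {
  manifest <- list(step = step, config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("accelcal")),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(outdir, paste0(step, "-manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

.ensure_outdir <- function(cfg) {
  if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
  cfg$output_dir
}

#' Run the calibration step
#'
#' Reads a calibration CSV (`subject_id, resting_vo2, speed, vo2,
#' counts_per_min`), computes MET values, fits the per-subject regressions
#' and cut points, fits the pooled mixed model, and writes
#' `individual-calibration.csv`, `group-model.csv` and a manifest to the
#' output directory. With `skip_bad = TRUE`, subjects whose fit fails are
#' dropped with a message instead of aborting the run.
#'
#' @param cfg A [run_config()] with `calibration_csv` set.
#' @return Invisibly, a list with `calibrations` (data frame) and
#'   `group_model`.
#' @export
run_calibrate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$calibration_csv)) stop("`calibration_csv` is not set", call. = FALSE)
  outdir <- .ensure_outdir(cfg)
  sessions <- read_calibration_csv(cfg$calibration_csv)
  message(sprintf("calibrate: %d subjects read from %s", length(sessions),
                  cfg$calibration_csv))
  cals <- list(); kept <- list()
  for (ses in sessions) {
    res <- tryCatch({
      ses2 <- compute_mets(ses, mode = cfg$met_mode)
      derive_icp(fit_individual(ses2, order = cfg$model_order),
                 target_met = cfg$target_met)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (!isTRUE(cfg$skip_bad)) {
        stop(sprintf("subject %s: %s", ses$subject_id, conditionMessage(res)),
             call. = FALSE)
      }
      message(sprintf("calibrate: skipping subject %s (%s)", ses$subject_id,
                      conditionMessage(res)))
      next
    }
    cals[[length(cals) + 1L]] <- res
    kept[[length(kept) + 1L]] <- compute_mets(ses, mode = cfg$met_mode)
  }
  message(sprintf("calibrate: %d of %d subjects calibrated, %d floored",
                  length(cals), length(sessions),
                  sum(vapply(cals, `[[`, logical(1), "floor_applied"))))
  tab <- calibration_table(cals)
  utils::write.csv(tab, file.path(outdir, "individual-calibration.csv"), row.names = FALSE)
  gm <- fit_group_model(kept, target_met = cfg$target_met)
  gm_df <- data.frame(beta0 = gm$beta0, beta1 = gm$beta1,
                      ci_beta0_lower = gm$ci_beta0[1], ci_beta0_upper = gm$ci_beta0[2],
                      ci_beta1_lower = gm$ci_beta1[1], ci_beta1_upper = gm$ci_beta1[2],
                      sigma2_u = gm$sigma2_u, rho = gm$rho, sigma2_e = gm$sigma2_e,
                      gcp = gm$gcp, gcp_rounded = gm$gcp_rounded)
  utils::write.csv(gm_df, file.path(outdir, "group-model.csv"), row.names = FALSE)
  .write_manifest(cfg, outdir, "calibrate")
  invisible(list(calibrations = tab, group_model = gm))
}

#' Run the free-living scoring step
#'
#' Scores each epoch file against each cut-point source listed in the
#' cut-point table (`subject_id, cut_point, source`), writing
#' `days-<source>.csv` and `subjects-<source>.csv` plus a manifest.
#'
#' @param cfg A [run_config()] with `epoch_files` (named character vector
#'   or list mapping subject_id to file path) and `cut_point_csv` set.
#' @return Invisibly, a named list per source with `days` and `subjects`
#'   data frames.
#' @export
run_score <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$epoch_files) || is.null(cfg$cut_point_csv)) {
    stop("`epoch_files` and `cut_point_csv` must be set", call. = FALSE)
  }
  outdir <- .ensure_outdir(cfg)
  cuts <- utils::read.csv(cfg$cut_point_csv, stringsAsFactors = FALSE)
  need <- c("subject_id", "cut_point", "source")
  if (!all(need %in% names(cuts))) {
    stop("cut-point table must have columns subject_id, cut_point, source", call. = FALSE)
  }
  files <- cfg$epoch_files
  out <- list()
  for (src in unique(cuts$source)) {
    sub_cuts <- cuts[cuts$source == src, ]
    day_rows <- list(); subj_rows <- list()
    for (k in seq_len(nrow(sub_cuts))) {
      sid <- sub_cuts$subject_id[k]
      if (!sid %in% names(files)) {
        message(sprintf("score: no epoch file for subject %s; skipped", sid))
        next
      }
      dialect <- epoch_dialect(header = cfg$dialect_header,
                               epoch_length = cfg$epoch_length, subject_id = sid)
      series <- read_epoch_csv(files[[sid]], dialect)
      res <- summarize_subject(series, cut_point = sub_cuts$cut_point[k],
                               min_days = cfg$min_days, min_wear = cfg$min_wear,
                               nw_window = cfg$nw_window, nw_allowance = cfg$nw_allowance,
                               bout_min = cfg$bout_min, bout_drop = cfg$bout_drop)
      res$days$source <- src; res$subject$source <- src
      day_rows[[length(day_rows) + 1L]] <- res$days
      subj_rows[[length(subj_rows) + 1L]] <- res$subject
    }
    days <- do.call(rbind, day_rows); subjects <- do.call(rbind, subj_rows)
    utils::write.csv(days, file.path(outdir, sprintf("days-%s.csv", src)), row.names = FALSE)
    utils::write.csv(subjects, file.path(outdir, sprintf("subjects-%s.csv", src)),
                     row.names = FALSE)
    message(sprintf("score [%s]: %d subjects, %d valid measurements", src,
                    nrow(subjects), sum(subjects$valid_measurement)))
    out[[src]] <- list(days = days, subjects = subjects)
  }
  .write_manifest(cfg, outdir, "score")
  invisible(out)
}

#' Run the method-comparison step
#'
#' Reads a tidy outcomes CSV (`subject_id, outcome, value, source`) with
#' exactly two sources, and for each outcome computes the Bland-Altman
#' agreement report (differences second source minus first); for the
#' bouted-MVPA outcome it additionally computes the guideline
#' reclassification table. Writes `agreement.csv` and a manifest.
#'
#' @param cfg A [run_config()] with `outcomes_csv` set.
#' @param bout_outcome Name of the bouted-MVPA outcome (default
#'   `"bouts_per_day"`).
#' @return Invisibly, a list with `agreement` (data frame, one row per
#'   outcome) and `reclassification` (or NULL).
#' @export
run_compare <- function(cfg, bout_outcome = "bouts_per_day") {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$outcomes_csv)) stop("`outcomes_csv` is not set", call. = FALSE)
  outdir <- .ensure_outdir(cfg)
  df <- utils::read.csv(cfg$outcomes_csv, stringsAsFactors = FALSE)
  need <- c("subject_id", "outcome", "value", "source")
  if (!all(need %in% names(df))) {
    stop("outcomes file must have columns subject_id, outcome, value, source", call. = FALSE)
  }
  sources <- sort(unique(df$source))
  if (length(sources) != 2L) stop("exactly two sources are required", call. = FALSE)
  rows <- list(); reclass <- NULL
  for (oc in unique(df$outcome)) {
    wide <- merge(df[df$outcome == oc & df$source == sources[1], c("subject_id", "value")],
                  df[df$outcome == oc & df$source == sources[2], c("subject_id", "value")],
                  by = "subject_id", suffixes = c("_a", "_b"))
    rep <- bland_altman(wide$value_a, wide$value_b, center = cfg$ba_center)
    rows[[oc]] <- data.frame(outcome = oc, n = rep$n,
                             central_diff = rep$central_diff, sd_diff = rep$sd_diff,
                             sem = rep$sem, loa = rep$loa,
                             limit_lower = rep$limits[1], limit_upper = rep$limits[2],
                             cv_percent = rep$cv_percent,
                             spearman_rho = rep$spearman_rho,
                             spearman_p = rep$spearman_p,
                             wilcoxon_p = rep$wilcoxon_p)
    if (oc == bout_outcome) {
      reclass <- guideline_reclassification(wide$value_a, wide$value_b,
                                            threshold = cfg$guideline_minutes)
      message(sprintf("compare: guideline reclassification %.0f%% agreement, kappa = %.2f",
                      reclass$agreement_percent, reclass$kappa))
    }
  }
  agreement <- do.call(rbind, rows)
  utils::write.csv(agreement, file.path(outdir, "agreement.csv"), row.names = FALSE)
  .write_manifest(cfg, outdir, "compare")
  invisible(list(agreement = agreement, reclassification = reclass))
}

#' Run the simulation step
#'
#' Generates a synthetic calibration cohort and a synthetic free-living
#' stream from the configured seed, writing `calibration.csv`,
#' `calibration-truth.csv`, one epoch CSV per simulated free-living
#' subject, `freeliving-truth.csv` and a manifest. Outputs are in the same
#' CSV dialects the analysis steps consume, so a full round trip
#' (simulate, calibrate, score, compare) needs no external data.
#'
#' @param cfg A [run_config()]; uses `seed`, `n_subjects`, `n_days`,
#'   `output_dir`.
#' @return Invisibly, a list with the generated objects.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  outdir <- .ensure_outdir(cfg)
  cs <- cohort_scenario(n_subjects = cfg$n_subjects, seed = cfg$seed)
  cohort <- generate_calibration_cohort(cs)
  cal_rows <- do.call(rbind, lapply(cohort$sessions, function(ses) {
    data.frame(subject_id = ses$subject_id, resting_vo2 = ses$resting_vo2,
               speed = ses$stages$speed, vo2 = ses$stages$vo2,
               counts_per_min = ses$stages$counts_per_min)
  }))
  utils::write.csv(cal_rows, file.path(outdir, "calibration.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(outdir, "calibration-truth.csv"),
                   row.names = FALSE)
  fs <- freeliving_scenario(n_days = cfg$n_days, seed = cfg$seed + 1L)
  fl <- generate_freeliving(fs)
  write_epoch_csv(fl$series, file.path(outdir, "freeliving-F01.csv"))
  utils::write.csv(fl$truth, file.path(outdir, "freeliving-truth.csv"), row.names = FALSE)
  message(sprintf("simulate: %d calibration subjects, %d free-living days",
                  length(cohort$sessions), cfg$n_days))
  .write_manifest(cfg, outdir, "simulate")
  invisible(list(cohort = cohort, freeliving = fl))
}
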