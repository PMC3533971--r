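#' Pooled mixed-model calibration and the group cut point (GCP)
#'
#' Fits the pooled count-to-MET model
#' \deqn{MET_{ij} = \beta_0 + \beta_1 \cdot counts_{ij} + u_i + e_{ij}}
#' across subjects by restricted maximum likelihood (REML), with a random
#' intercept per subject, \eqn{u_i \sim N(0, \sigma^2_u)}, and an AR(1)
#' covariance structure over the ordered treadmill stages within subject
#' for the residuals \eqn{e_{ij}} (treadmill speed as the repeated
#' measure). The group cut point is the counts/min at which the fixed-effect
#' line crosses the target MET level:
#' \eqn{GCP = (target - \beta_0)/\beta_1}.
#'
#' REML is maximised by numerical optimisation over
#' \eqn{(\log\sigma^2_u, \mathrm{atanh}\,\rho, \log\sigma^2_e)} with the
#' fixed effects profiled out by generalised least squares at each step;
#' the optimiser is restarted from three fixed initial points to guard
#' against local optima. Perfectly fitting (noise-free) data make the REML
#' objective unbounded, so an exact pooled OLS fit is detected up front and
#' returned with zero variance components and a warning.
#'
#' @param sessions List of [calibration_session()] objects (>= 2 subjects,
#'   each >= 2 stages) with METs computed.
#' @param target_met Target MET level for the cut point (default 3).
#' @param conf_level Confidence level for Wald intervals on the fixed
#'   effects (default 0.95).
#' @return An object of class `group_model` with elements `beta0`, `beta1`,
#'   `se_beta0`, `se_beta1`, `ci_beta0`, `ci_beta1`, `sigma2_u`, `rho`,
#'   `sigma2_e`, `gcp` (unrounded counts/min), `gcp_rounded`, `logLik_reml`,
#'   `n_subjects`, `n_obs`, `convergence`.
#' @examples
#' sessions <- lapply(1:3, function(i) {
#'   counts <- c(200, 600, 1000, 1400, 1800)
#'   compute_mets(calibration_session(paste0("S", i), 3.0,
#'     data.frame(speed = 2:6, vo2 = 3.0 * (2.5276 + 0.000690 * counts),
#'                counts_per_min = counts)))
#' })
#' fit <- suppressWarnings(fit_group_model(sessions))
#' fit$gcp_rounded  # 685
#' @export
fit_group_model <- function(sessions, target_met = 3, conf_level = 0.95) {
  dat <- .prep_group_data(sessions)
  m <- dat$m; N <- dat$N; p <- dat$p

  ols <- stats::lm.fit(dat$X, dat$y)
  rss <- sum(ols$residuals^2)
  scale_y <- max(stats::var(dat$y), .Machine$double.eps)
  if (rss < 1e-10 * scale_y * N) {
    warning("data fit the fixed-effect line exactly; variance components set to 0",
            call. = FALSE)
    beta <- unname(ols$coefficients)
    return(.group_model_result(beta, c(0, 0), 0, 0, 0, target_met, conf_level,
                               logLik = Inf, m = m, N = N, convergence = 0L))
  }

  obj <- function(eta) {
    .group_neg2reml(dat, exp(eta[1]), tanh(eta[2]), exp(eta[3]))$value
  }
  v0 <- rss / (N - p)
  starts <- list(
    c(log(0.5 * v0), atanh(0), log(0.5 * v0)),
    c(log(0.1 * v0), atanh(0.6), log(0.9 * v0)),
    c(log(0.9 * v0), atanh(-0.4), log(0.2 * v0))
  )
  best <- NULL
  codes <- integer(0)
  for (st0 in starts) {
    opt <- stats::optim(st0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    codes <- c(codes, opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (all(codes != 0L) || best$value >= 1e10) {
    stop(sprintf("REML optimisation failed to converge (best -2logLik = %.4f)",
                 best$value), call. = FALSE)
  }
  eta <- best$par
  s2u <- exp(eta[1]); rho <- tanh(eta[2]); s2e <- exp(eta[3])
  if (abs(rho) > 0.99) warning("AR(1) correlation estimate is on the boundary",
                               call. = FALSE)
  at <- .group_neg2reml(dat, s2u, rho, s2e)
  .group_model_result(at$beta, sqrt(diag(at$vcov_beta)), s2u, rho, s2e,
                      target_met, conf_level, logLik = -best$value / 2,
                      m = m, N = N, convergence = min(codes))
}

# Validate sessions and assemble per-subject response/design/stage-rank lists.
.prep_group_data <- function(sessions) {
  if (length(sessions) < 2L) stop("at least 2 subjects are required", call. = FALSE)
  ok <- vapply(sessions, inherits, logical(1), "calibration_session")
  if (!all(ok)) stop("`sessions` must be a list of calibration_session objects", call. = FALSE)
  ylist <- list(); Xlist <- list(); ranklist <- list()
  for (s in sessions) {
    st <- s$stages
    if (anyNA(st$met)) stop("METs not computed; call compute_mets() first", call. = FALSE)
    ord <- order(st$speed)
    ylist[[length(ylist) + 1L]] <- st$met[ord]
    Xlist[[length(Xlist) + 1L]] <- cbind(1, st$counts_per_min[ord])
    ranklist[[length(ranklist) + 1L]] <- seq_along(ord)
  }
  list(ylist = ylist, Xlist = Xlist, ranklist = ranklist,
       keys = vapply(ranklist, paste, character(1), collapse = ","),
       m = length(ylist), N = sum(lengths(ylist)), p = 2L,
       X = do.call(rbind, Xlist), y = unlist(ylist))
}

# -2 * restricted log-likelihood at fixed variance parameters, with the
# fixed effects profiled out by GLS. Returns the profiled beta and its
# covariance alongside the objective value. Ill-conditioned parameter
# values return a large finite value so the optimizer can back away.
.group_neg2reml <- function(dat, s2u, rho, s2e) {
  p <- dat$p
  bad <- list(value = 1e10, beta = rep(NA_real_, p), vcov_beta = NULL)
  if (!is.finite(s2u) || !is.finite(s2e) || !is.finite(rho) ||
      s2u < 0 || s2e <= 0 || abs(rho) >= 1) {
    return(bad)
  }
  chol_cache <- list()
  for (k in unique(dat$keys)) {
    r <- dat$ranklist[[match(k, dat$keys)]]
    V <- s2u + s2e * rho^abs(outer(r, r, "-"))  # random intercept adds s2u everywhere
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(bad)
    chol_cache[[k]] <- ch
  }
  XtVX <- matrix(0, p, p); XtVy <- numeric(p)
  logdet <- 0
  parts <- vector("list", dat$m)
  for (i in seq_len(dat$m)) {
    ch <- chol_cache[[dat$keys[i]]]
    logdet <- logdet + 2 * sum(log(diag(ch)))
    Z <- backsolve(ch, cbind(dat$Xlist[[i]], dat$ylist[[i]]), transpose = TRUE)
    Zx <- Z[, 1:p, drop = FALSE]; Zy <- Z[, p + 1L]
    XtVX <- XtVX + crossprod(Zx)
    XtVy <- XtVy + crossprod(Zx, Zy)
    parts[[i]] <- list(Zx = Zx, Zy = Zy)
  }
  XtVX_chol <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(XtVX_chol)) return(bad)
  beta <- backsolve(XtVX_chol, backsolve(XtVX_chol, XtVy, transpose = TRUE))
  quad <- 0
  for (i in seq_len(dat$m)) {
    e <- parts[[i]]$Zy - parts[[i]]$Zx %*% beta
    quad <- quad + sum(e^2)
  }
  val <- (dat$N - p) * log(2 * pi) + logdet + 2 * sum(log(diag(XtVX_chol))) + quad
  if (!is.finite(val)) return(bad)
  list(value = val, beta = drop(beta), vcov_beta = chol2inv(XtVX_chol))
}

# Evaluate -2 REML at fixed variance parameters for a list of sessions
# (used to check that the optimized objective is no worse than at any
# reference parameter value).
reml_objective <- function(sessions, sigma2_u, rho, sigma2_e) {
  .group_neg2reml(.prep_group_data(sessions), sigma2_u, rho, sigma2_e)$value
}

# Profiled GLS fixed effects at fixed variance parameters.
gls_fixed_effects <- function(sessions, sigma2_u, rho, sigma2_e) {
  .group_neg2reml(.prep_group_data(sessions), sigma2_u, rho, sigma2_e)$beta
}

.group_model_result <- function(beta, se, s2u, rho, s2e, target_met, conf_level,
                                logLik, m, N, convergence) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (beta[2] == 0) stop("fixed slope is zero; no finite cut point", call. = FALSE)
  gcp <- (target_met - beta[1]) / beta[2]
  structure(list(
    beta0 = beta[1], beta1 = beta[2],
    se_beta0 = se[1], se_beta1 = se[2],
    ci_beta0 = beta[1] + c(-1, 1) * z * se[1],
    ci_beta1 = beta[2] + c(-1, 1) * z * se[2],
    sigma2_u = s2u, rho = rho, sigma2_e = s2e,
    target_met = target_met, conf_level = conf_level,
    gcp = gcp, gcp_rounded = round(gcp),
    logLik_reml = logLik, n_subjects = m, n_obs = N,
    convergence = convergence
  ), class = "group_model")
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("<group_model> %d subjects, %d observations (REML)\n",
              x$n_subjects, x$n_obs))
  cat(sprintf("  MET = %.4f + %.6f * counts/min\n", x$beta0, x$beta1))
  cat(sprintf("  %d%% CI intercept: %.4f to %.4f; slope: %.6f to %.6f\n",
              round(100 * x$conf_level), x$ci_beta0[1], x$ci_beta0[2],
              x$ci_beta1[1], x$ci_beta1[2]))
  cat(sprintf("  sigma2_u = %.4g, rho = %.3f, sigma2_e = %.4g\n",
              x$sigma2_u, x$rho, x$sigma2_e))
  cat(sprintf("  GCP at %g METs: %.1f counts/min (rounded: %d)\n",
              x$target_met, x$gcp, as.integer(x$gcp_rounded)))
  invisible(x)
}

#' Solve a fixed count-to-MET line for its cut point
#'
#' Utility for turning published calibration coefficients into a cut
#' point: solves `target_met = intercept + slope * counts` for counts.
#'
#' @param intercept,slope Line coefficients (METs; METs per count/min).
#' @param target_met Target MET level (default 3).
#' @return Counts/min at the crossing (unrounded).
#' @examples
#' cut_point_from_line(2.5276, 0.000690)  # ~684.6 -> rounds to 685
#' @export
cut_point_from_line <- function(intercept, slope, target_met = 3) {
  if (slope == 0) stop("slope is zero; no finite cut point", call. = FALSE)
  (target_met - intercept) / slope
}
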