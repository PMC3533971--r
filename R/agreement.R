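#' Bland-Altman agreement with SEM and limits of agreement
#'
#' Quantifies agreement between two measures of the same quantity (e.g.
#' individual cut points from the right vs. the left hip). Differences are
#' `d = y - x`. The standard error of measurement and the limits of
#' agreement follow the typical-error convention:
#' `SEM = sd(d) / sqrt(2)` and `LoA = SEM * sqrt(2) * 1.96` (algebraically
#' `1.96 * sd(d)`), so `LoA` is the 95% half-width around the central
#' difference. The limits are centred on the median difference by default
#' (robust to the skewed cut-point differences seen in practice); the mean
#' is available for the conventional Bland-Altman plot.
#'
#' @param x,y Numeric vectors of paired measurements (same units), length
#'   >= 3, no missing values.
#' @param center `"median"` (default) or `"mean"`: the central difference
#'   on which the limits are centred.
#' @param conf_z Normal quantile for the limits (default 1.96).
#' @return An object of class `agreement_report`: `n`, `mean_diff`,
#'   `median_diff`, `iqr_diff`, `central_diff`, `sd_diff`, `sem`, `loa`,
#'   `limits` (lower, upper), `cv_percent`, `spearman_rho`, `spearman_p`,
#'   `wilcoxon_p`.
#' @examples
#' right <- c(900, 1200, 1500, 700, 1100)
#' left  <- c(950, 1100, 1600, 820, 1050)
#' bland_altman(right, left)
#' @export
bland_altman <- function(x, y, center = c("median", "mean"), conf_z = 1.96) {
  center <- match.arg(center)
  .check_paired(x, y, min_n = 3L)
  d <- y - x
  sd_diff <- stats::sd(d)
  if (sd_diff == 0) warning("zero variance in differences; limits collapse to the center",
                            call. = FALSE)
  sem <- sd_diff / sqrt(2)
  loa <- sem * sqrt(2) * conf_z
  central <- if (center == "median") stats::median(d) else mean(d)
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  wil <- wilcoxon_signed_rank(d)
  structure(list(
    n = length(d), center = center,
    mean_diff = mean(d), median_diff = stats::median(d),
    iqr_diff = stats::IQR(d), central_diff = central,
    sd_diff = sd_diff, sem = sem, loa = loa,
    limits = c(lower = central - loa, upper = central + loa),
    cv_percent = if (mean(c(x, y)) > 0) cv_between_methods(x, y) else NA_real_,
    spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
    wilcoxon_p = wil$p_value
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d pairs\n", x$n))
  cat(sprintf("  difference (y - x): mean %.2f, median %.2f (IQR %.2f)\n",
              x$mean_diff, x$median_diff, x$iqr_diff))
  cat(sprintf("  SEM = %.2f, LoA = %.2f; 95%% limits (%s-centred): %.1f to %.1f\n",
              x$sem, x$loa, x$center, x$limits[1], x$limits[2]))
  cat(sprintf("  CV = %.1f%%, Spearman rho = %.2f (p = %.3f), Wilcoxon p = %.3f\n",
              x$cv_percent, x$spearman_rho, x$spearman_p, x$wilcoxon_p))
  invisible(x)
}

.check_paired <- function(x, y, min_n = 3L) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < min_n) stop(sprintf("at least %d pairs are required", min_n), call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("paired measures must be pairwise complete", call. = FALSE)
  invisible(TRUE)
}

#' Between-method coefficient of variation
#'
#' `CV = 100 * sd(y - x) / mean(c(x, y))`: the standard deviation of the
#' paired differences expressed as a percentage of the grand mean of all
#' observations. This is the typical-error-as-CV convention; a pure
#' constant bias between methods contributes nothing. An alternative
#' (`method = "per_pair"`) averages within-pair CVs instead.
#'
#' @param x,y Paired measurements.
#' @param method `"diff_sd"` (default) or `"per_pair"`.
#' @return CV in percent.
#' @examples
#' cv_between_methods(c(40, 80, 120), c(60, 60, 120))  # 25
#' @export
cv_between_methods <- function(x, y, method = c("diff_sd", "per_pair")) {
  method <- match.arg(method)
  .check_paired(x, y, min_n = 2L)
  if (method == "per_pair") {
    pair_means <- (x + y) / 2
    if (any(pair_means <= 0)) stop("per-pair CV requires positive pair means", call. = FALSE)
    pair_sd <- abs(y - x) / sqrt(2)
    return(100 * mean(pair_sd / pair_means))
  }
  grand_mean <- mean(c(x, y))
  if (grand_mean <= 0) stop("grand mean must be positive for a CV", call. = FALSE)
  100 * stats::sd(y - x) / grand_mean
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Tests whether paired differences are symmetric about zero. Zero
#' differences are dropped. For n <= 25 non-zero untied differences the
#' exact null distribution of the signed-rank statistic is used
#' (enumeration over sign patterns via the signrank distribution);
#' otherwise, or in the presence of ties, a normal approximation with
#' continuity and tie corrections is applied.
#'
#' @param x Differences, or the first member of each pair if `y` is given.
#' @param y Optional second member; differences are `x - y`.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return A list with `statistic` (V, the sum of ranks of positive
#'   differences), `n` (non-zero differences), `p_value`, and `method`.
#' @examples
#' wilcoxon_signed_rank(c(1.2, 0.8, 2.1, 0.3, 1.7, 0.9))  # all positive, n = 6
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else x - y
  if (anyNA(d)) stop("differences must not contain NA", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1", call. = FALSE)
    return(list(statistic = NA_real_, n = 0L, p_value = 1, method = "degenerate"))
  }
  if (n < 5L) warning("fewer than 5 non-zero differences; the test has little power",
                      call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_max) {
    # exact two-sided p from the enumerated null of the signed-rank statistic
    p <- 2 * min(stats::psignrank(v, n), stats::psignrank(v - 1, n, lower.tail = FALSE))
    p <- min(1, p)
    return(list(statistic = v, n = n, p_value = p, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(statistic = v, n = n, p_value = min(1, p), method = "normal")
}

#' Partial correlations from a multiple linear regression
#'
#' Fits `outcome ~ predictors` by least squares and reports, for each
#' predictor, the partial correlation with the outcome given the other
#' predictors, computed from the coefficient's t statistic as
#' `r = t / sqrt(t^2 + df_residual)` (signed like the coefficient).
#'
#' @param outcome Numeric response vector.
#' @param predictors Data frame or matrix of numeric predictors (named
#'   columns).
#' @return An object of class `association_report`: `coefficients` (data
#'   frame with estimate, t, partial_r, p per predictor), `r_squared`,
#'   `f_stat`, `f_p`, `df_residual`, `n`.
#' @export
partial_correlations <- function(outcome, predictors) {
  predictors <- as.data.frame(predictors)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors)))) {
    stop("predictors must be named", call. = FALSE)
  }
  n <- length(outcome)
  if (nrow(predictors) != n) stop("outcome and predictors must have equal length", call. = FALSE)
  if (n <= ncol(predictors) + 1L) {
    stop("need more observations than predictors + 1", call. = FALSE)
  }
  dat <- cbind(data.frame(.outcome = outcome), predictors)
  fit <- stats::lm(.outcome ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)
  tt <- sm$coefficients[-1, , drop = FALSE]
  dfres <- fit$df.residual
  coefs <- data.frame(
    term = rownames(tt),
    estimate = tt[, "Estimate"],
    t = tt[, "t value"],
    partial_r = tt[, "t value"] / sqrt(tt[, "t value"]^2 + dfres),
    p = tt[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 f_stat = unname(sm$fstatistic["value"]),
                 f_p = stats::pf(sm$fstatistic["value"], sm$fstatistic["numdf"],
                                 sm$fstatistic["dendf"], lower.tail = FALSE),
                 df_residual = dfres, n = n),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf("<association_report> n = %d, R^2 = %.3f, F = %.1f (p = %.3g)\n",
              x$n, x$r_squared, x$f_stat, x$f_p))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Polynomial association between an outcome and a single predictor
#'
#' Least-squares polynomial fit of degree 1 or 2 (raw polynomial terms),
#' e.g. the curvilinear relation between individual cut points and minutes
#' of MVPA/day. `compare_degrees()` tests the quadratic term against the
#' linear model with a nested F-test.
#'
#' @param outcome Numeric response.
#' @param x Numeric predictor.
#' @param degree 1 or 2.
#' @return An `association_report` (coefficients carry raw polynomial
#'   terms; `partial_r` as in [partial_correlations()]).
#' @export
polynomial_association <- function(outcome, x, degree = 2L) {
  degree <- as.integer(degree)
  if (!degree %in% c(1L, 2L)) stop("`degree` must be 1 or 2", call. = FALSE)
  if (length(outcome) != length(x)) stop("`outcome` and `x` must have equal length", call. = FALSE)
  if (length(outcome) <= degree + 1L) stop("too few observations for this degree", call. = FALSE)
  preds <- data.frame(x = x)
  if (degree == 2L) preds$x_squared <- x^2
  partial_correlations(outcome, preds)
}

#' @rdname polynomial_association
#' @return `compare_degrees()`: a list with the nested-F statistic and
#'   p-value for degree 2 vs. degree 1, plus both models' R-squared.
#' @export
compare_degrees <- function(outcome, x) {
  f1 <- stats::lm(outcome ~ x)
  f2 <- stats::lm(outcome ~ x + I(x^2))
  an <- stats::anova(f1, f2)
  list(f_stat = an$F[2], p_value = an$`Pr(>F)`[2],
       r_squared_linear = summary(f1)$r.squared,
       r_squared_quadratic = summary(f2)$r.squared)
}

#' Guideline reclassification between two cut-point sources
#'
#' Classifies each subject as meeting or not meeting a physical-activity
#' guideline (>= 30 min/day of bouted MVPA by default) under two cut-point
#' sources, and quantifies agreement with the observed percent agreement
#' and Cohen's kappa (p-value by normal approximation under the
#' independence null).
#'
#' @param bouts_a,bouts_b Paired minutes/day of bouted MVPA under the two
#'   sources (e.g. individual vs. group cut points).
#' @param threshold Guideline threshold in minutes/day (default 30).
#' @return A list with `table` (2x2 contingency, A in rows, B in columns),
#'   `agreement_percent`, `kappa`, `kappa_p`, `n`. With degenerate margins
#'   kappa is `NA` and a warning is raised; agreement is still returned.
#' @examples
#' guideline_reclassification(c(40, 10, 35, 50), c(35, 5, 20, 60))
#' @export
guideline_reclassification <- function(bouts_a, bouts_b, threshold = 30) {
  .check_paired(bouts_a, bouts_b, min_n = 2L)
  a_meets <- factor(bouts_a >= threshold, levels = c(FALSE, TRUE),
                    labels = c("below", "meets"))
  b_meets <- factor(bouts_b >= threshold, levels = c(FALSE, TRUE),
                    labels = c("below", "meets"))
  tab <- table(a = a_meets, b = b_meets)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  row_p <- rowSums(tab) / n
  col_p <- colSums(tab) / n
  pe <- sum(row_p * col_p)
  if (pe >= 1) {
    warning("degenerate margins (all subjects in one class); kappa undefined",
            call. = FALSE)
    kappa <- NA_real_; kappa_p <- NA_real_
  } else {
    kappa <- (po - pe) / (1 - pe)
    # Fleiss large-sample SE under the null of chance agreement
    se0 <- sqrt(max(0, pe + pe^2 - sum(row_p * col_p * (row_p + col_p)))) /
      ((1 - pe) * sqrt(n))
    kappa_p <- if (se0 > 0) 2 * stats::pnorm(-abs(kappa / se0)) else NA_real_
  }
  list(table = tab, agreement_percent = 100 * po, kappa = kappa,
       kappa_p = kappa_p, n = n)
}
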