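test_that("LoA equals 1.96 * sd of differences and limits sit symmetric on the center", {
  set.seed(3)
  for (k in 1:10) {
    x <- rnorm(15, 1000, 300)
    y <- x + rnorm(15, 20, 150)
    rep <- bland_altman(x, y)
    expect_equal(rep$loa, 1.96 * rep$sd_diff, tolerance = 1e-12)
    expect_equal(unname(rep$limits["upper"] - rep$central_diff),
                 unname(rep$central_diff - rep$limits["lower"]), tolerance = 1e-10)
    # swapping the measures negates the center and limits, keeps sem/loa/cv
    swapped <- bland_altman(y, x)
    expect_equal(swapped$central_diff, -rep$central_diff)
    expect_equal(unname(swapped$limits), unname(-rev(rep$limits)))
    expect_equal(swapped$sem, rep$sem)
    expect_equal(swapped$cv_percent, rep$cv_percent)
  }
  expect_warning(expect_warning(bland_altman(1:5 * 100, 1:5 * 100),
                                "zero variance"),
                 "all differences")
  ident <- suppressWarnings(bland_altman(1:5 * 100, 1:5 * 100))
  expect_equal(ident$sem, 0)
  expect_equal(unname(ident$limits), c(0, 0))
})

test_that("between-method CV matches hand computation and ignores pure bias", {
  expect_equal(cv_between_methods(c(10, 10, 10), c(20, 20, 20)), 0)
  expect_equal(cv_between_methods(c(40, 80, 120), c(60, 60, 120)), 25)
  expect_equal(cv_between_methods(c(5, 6, 7), c(5, 6, 7)), 0)
  expect_error(cv_between_methods(c(-10, -20), c(10, 20)), "positive")
})

test_that("signed-rank p-values match full enumeration and the stats reference", {
  d_all_pos <- c(1.2, 0.8, 2.1, 0.3, 1.7, 0.9)
  res <- wilcoxon_signed_rank(d_all_pos)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 2 / 64)

  set.seed(8)
  for (k in 1:10) {
    d <- round(rnorm(sample(6:10, 1), 0.2, 1), 3)
    d <- d[d != 0]
    if (any(duplicated(abs(d)))) next
    mine <- wilcoxon_signed_rank(d)
    expect_equal(mine$p_value, enumerate_signed_rank_p(d), tolerance = 1e-12)
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(mine$statistic), unname(ref$statistic))
  }

  # symmetric +/- pairs leave the statistic at its null center
  sym <- suppressWarnings(wilcoxon_signed_rank(c(1, -1.5, 2, -2.5) + 0.01 * (1:4)))
  expect_gt(sym$p_value, 0.5)
  expect_warning(z <- wilcoxon_signed_rank(rep(0, 4)), "all differences")
  expect_equal(z$p_value, 1)
  expect_warning(wilcoxon_signed_rank(c(1, 2, -0.5)), "little power")
})

test_that("partial correlations reduce to Pearson r and recover planted structure", {
  set.seed(21)
  x <- rnorm(40); yy <- 2 * x + rnorm(40)
  rep1 <- partial_correlations(yy, data.frame(x = x))
  expect_equal(rep1$coefficients$partial_r, cor(yy, x), tolerance = 1e-10)

  # orthogonalized noise predictor has partial r near 0
  z <- residuals(lm(rnorm(40) ~ x + yy))
  rep2 <- partial_correlations(yy, data.frame(x = x, z = z))
  expect_lt(abs(rep2$coefficients$partial_r[2]), 1e-8)

  # residual-on-residual correlation is the independent definition
  set.seed(22)
  n <- 200
  a <- rnorm(n); b <- 0.5 * a + rnorm(n)
  y <- 1 + 0.8 * a - 0.6 * b + rnorm(n)
  rep3 <- partial_correlations(y, data.frame(a = a, b = b))
  r_oracle <- cor(residuals(lm(y ~ b)), residuals(lm(a ~ b)))
  expect_equal(rep3$coefficients$partial_r[1], r_oracle, tolerance = 1e-10)

  expect_error(partial_correlations(y, data.frame(a = a, a2 = 2 * a)),
               "collinear")
})

test_that("polynomial association captures curvature and the nested F-test detects it", {
  x <- seq(100, 2500, length.out = 30)
  y_exact <- 200 - 0.1 * x + 2e-5 * x^2
  rep2 <- suppressWarnings(polynomial_association(y_exact, x, degree = 2))
  expect_equal(rep2$r_squared, 1, tolerance = 1e-10)

  set.seed(31)
  y_noise <- rnorm(30)
  rep0 <- polynomial_association(y_noise, x, degree = 1)
  expect_lt(rep0$r_squared, 0.3)

  cmp <- compare_degrees(y_exact + rnorm(30, 0, 5), x)
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$r_squared_quadratic, cmp$r_squared_linear)
})

test_that("reclassification kappa matches the hand-worked 2x2 case", {
  # contingency (meets/meets = 3, meets/below = 1, below/meets = 2, below/below = 4)
  a <- c(rep(40, 3), rep(40, 1), rep(10, 2), rep(10, 4))
  b <- c(rep(40, 3), rep(10, 1), rep(40, 2), rep(10, 4))
  res <- guideline_reclassification(a, b, threshold = 30)
  expect_equal(res$agreement_percent, 70)
  expect_equal(res$kappa, 0.4, tolerance = 1e-12)

  ident <- guideline_reclassification(c(40, 10, 50), c(35, 5, 45))
  expect_equal(ident$agreement_percent, 100)
  expect_equal(ident$kappa, 1)

  # independent classifications with balanced margins: kappa near 0
  set.seed(41)
  big_a <- sample(c(10, 50), 4000, replace = TRUE)
  big_b <- sample(c(10, 50), 4000, replace = TRUE)
  res0 <- guideline_reclassification(big_a, big_b)
  expect_lt(abs(res0$kappa), 0.05)
  expect_gt(res0$kappa_p, 0.01)

  # label swap leaves kappa unchanged; degenerate margins flag NA
  swapped <- guideline_reclassification(-a + 60, -b + 60, threshold = 30)
  expect_equal(swapped$kappa, res$kappa, tolerance = 1e-12)
  expect_warning(deg <- guideline_reclassification(c(40, 45, 50), c(41, 46, 51)),
                 "degenerate")
  expect_true(is.na(deg$kappa))
  expect_equal(deg$agreement_percent, 100)
})
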