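# Evaluation layer: confusion, R^2, Bland-Altman, LOD, calibration,
# baselines, Welch's t-test, clinical calls.

test_that("confusion matrix and accuracies", {
  cm <- confusion_and_accuracy(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(cm$overall_accuracy, 1)
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0)

  # 2-class case with counts [[8,2],[1,9]] -> 17/20
  truth <- rep(c("x", "y"), times = c(10, 10))
  pred <- c(rep("x", 8), rep("y", 2), rep("x", 1), rep("y", 9))
  cm2 <- confusion_and_accuracy(truth, pred)
  expect_equal(unclass(cm2$counts), matrix(c(8, 1, 2, 9), 2),
               ignore_attr = TRUE)
  expect_equal(cm2$overall_accuracy, 0.85)
  expect_equal(cm2$macro_recall, (0.8 + 0.9) / 2)

  # permutation invariance
  perm <- sample(20)
  cm3 <- confusion_and_accuracy(truth[perm], pred[perm])
  expect_equal(unclass(cm3$counts), unclass(cm2$counts))

  expect_error(confusion_and_accuracy(c("a"), c("a", "b")), "equal")
})

test_that("r_squared: perfect, sign-blind, covariance oracle, errors", {
  x <- c(1, 2, 3, 5)
  expect_equal(r_squared(x, x), 1)
  expect_equal(r_squared(-x, x), 1)
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(20)
    b <- rnorm(20)
    oracle <- (mean(a * b) - mean(a) * mean(b))^2 /
      ((mean(a^2) - mean(a)^2) * (mean(b^2) - mean(b)^2))
    expect_equal(r_squared(a, b), oracle, tolerance = 1e-12)
  }
  expect_error(r_squared(rep(1, 5), 1:5), "constant")
  expect_error(r_squared(1, 1), "n >= 2")
})

test_that("Bland-Altman: exact cases, coverage of Gaussian errors, and the
           within-limits characterisation", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(ba0$fraction_within, 1)

  ba1 <- bland_altman(c(0, 1, 2), c(1, 1, 1))   # differences -1, 0, 1
  expect_equal(ba1$bias, 0)
  expect_equal(ba1$sd_diff, 1)
  expect_equal(c(ba1$loa_low, ba1$loa_high), c(-1.96, 1.96))
  expect_equal(ba1$fraction_within, 1)

  # 1000 Gaussian differences: empirical coverage of the estimated limits
  # is close to the nominal ~95%
  # binomial SE at n = 1000 is ~0.007; allow ~3 SE around nominal
  set.seed(314)
  d <- rnorm(1000, 0, 0.05)
  ba2 <- bland_altman(d, numeric(1000))
  expect_equal(ba2$fraction_within, 0.95, tolerance = 0.022 / 0.95)

  expect_error(bland_altman(1:2, 1:2), "n >= 3")

  # fraction_within = 1 exactly when all |d - bias| <= 1.96 sd
  set.seed(99)
  for (i in 1:20) {
    d <- rnorm(30)
    ba <- bland_altman(d, numeric(30))
    expect_equal(ba$fraction_within == 1,
                 all(abs(d - ba$bias) <= 1.96 * ba$sd_diff + 1e-12))
  }
})

test_that("IUPAC LOD arithmetic and linearity in the blank SD", {
  expect_equal(lod(0.0022, 0.0021)$lod_pg_ml, 8.50, tolerance = 1e-9)
  expect_equal(lod(0.0025, 0.0026)$lod_pg_ml, 10.30, tolerance = 1e-9)
  expect_equal(lod(0, 0)$lod, 0)
  expect_error(lod(0.01, -1), ">= 0")
  # linear in blank_sd with coefficient exactly 3
  sds <- c(0.001, 0.002, 0.005, 0.01)
  lods <- vapply(sds, function(s) lod(0.002, s)$lod, numeric(1))
  expect_equal(diff(lods) / diff(sds), rep(3, 3), tolerance = 1e-12)
  expect_true(all(lods >= 0.002))
})

test_that("linear calibration over the LDR", {
  d0 <- generate_dataset(n_per_level = 3, params = noiseless_params(),
                         seed = 1)
  p <- assay_params()
  fit <- linear_fit_ldr(d0$true_conc_ng_ml, colorimetric_intensity(d0, p))
  # slope within 10% of the generator's linear slope (saturation curvature)
  expect_equal(fit$slope, p$linear_slope, tolerance = 0.10)
  expect_gt(fit$r_squared, 0.99)
  expect_equal(fit$n, sum(d0$true_conc_ng_ml <= 0.4))

  # adding a constant moves the intercept, not the slope
  y <- colorimetric_intensity(d0, p)
  fit2 <- linear_fit_ldr(d0$true_conc_ng_ml, y + 0.5)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-10)
  expect_equal(fit2$intercept, fit$intercept + 0.5, tolerance = 1e-10)

  expect_error(linear_fit_ldr(c(0.1, 0.1, 0.1), c(1, 2, 3)),
               "distinct concentrations")
  expect_error(linear_fit_ldr(c(1, 2), c(1, 2)), "at least 3 points")
})

test_that("baseline fits: ideal linear data, saturation penalty, ranking
           against the cross-validated GPR", {
  # perfectly linear single-channel data -> R^2 = 1
  conc <- seq(0, 0.4, by = 0.05)
  rgb <- data.frame(R = 235 - 10 * conc, G = 235 - 120 * conc,
                    B = 235 - 72 * conc)
  expect_equal(baseline_channel_fit(rgb, conc, "G")$r_squared, 1,
               tolerance = 1e-12)
  expect_equal(baseline_euclidean_fit(rgb, conc)$r_squared, 1,
               tolerance = 1e-12)

  # full saturating ladder: every baseline sits strictly below the pooled
  # cross-validated GPR R^2, and the improvement percentage is positive
  d <- pbs_dataset()
  gpr_r2 <- pbs_gpr_cv()$metrics$r_squared
  eu <- baseline_euclidean_fit(d, d$true_conc_ng_ml)
  expect_lt(eu$r_squared, gpr_r2)
  expect_gt(improvement_percent(gpr_r2, eu$r_squared), 0)
  for (ch in c("R", "G", "B")) {
    bc <- baseline_channel_fit(d, d$true_conc_ng_ml, ch)
    expect_lt(bc$r_squared, 1)
    expect_lt(bc$r_squared, gpr_r2)
  }

  expect_error(baseline_euclidean_fit(rgb, conc + 1), "no blank")
})

test_that("Welch's t-test: degenerate cases and agreement with the
           independent oracle", {
  expect_equal(welch_ttest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(welch_ttest(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_ttest(c(2, 2), c(2, 2))$p, 1)    # zero variance, equal
  expect_equal(welch_ttest(c(3, 3), c(1, 1))$p, 0)    # zero variance, apart

  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    b <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
    res <- welch_ttest(a, b)
    oracle <- stats::t.test(a, b)     # Welch by default
    expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(res$df, unname(oracle$parameter), tolerance = 1e-10)
    expect_equal(res$p, oracle$p.value, tolerance = 1e-10)
  }
  expect_error(welch_ttest(1, c(1, 2)), "n >= 2")
})

test_that("clinical interval call", {
  expect_equal(classify_clinical(10, 0.3), "positive")
  expect_equal(classify_clinical(0, 0.3), "negative")
  expect_equal(classify_clinical(0.3, 0.3), "positive")   # boundary inclusive
  expect_error(classify_clinical(1), "threshold")

  # six blinded samples, three drawn above the cut-off -> three positives
  preds <- c(0.05, 0.8, 0.1, 1.2, 0.02, 0.6)
  calls <- classify_clinical(preds, 0.3)
  expect_equal(sum(calls == "positive"), 3)
  expect_equal(calls, ifelse(preds >= 0.3, "positive", "negative"))
})
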