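# Evaluation and decision layer: confusion matrix, R^2, Bland-Altman,
# linear calibration + IUPAC LOD, baseline fits, Welch's t-test, and the
# clinical concentration-interval call.

#' Confusion matrix and accuracies
#'
#' Tallies true x predicted counts. `overall_accuracy` is the trace divided
#' by the total; `macro_recall` is the mean per-class recall
#' (diagonal / row sum) over classes that actually occur.
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @return An object of class `uelfa_confusion`: `counts` (true x predicted
#'   matrix), `overall_accuracy`, `macro_recall`.
#' @export
confusion_and_accuracy <- function(true_labels, pred_labels) {
  assert_that(length(true_labels) == length(pred_labels) &&
                length(true_labels) >= 1,
              "label vectors must have equal, non-zero length")
  lev <- sort(unique(c(as.character(true_labels), as.character(pred_labels))))
  tl <- factor(as.character(true_labels), levels = lev)
  pl <- factor(as.character(pred_labels), levels = lev)
  counts <- table(true = tl, predicted = pl)
  rs <- rowSums(counts)
  recall <- diag(counts)[rs > 0] / rs[rs > 0]
  structure(
    list(counts = counts,
         overall_accuracy = sum(diag(counts)) / sum(counts),
         macro_recall = mean(recall)),
    class = "uelfa_confusion"
  )
}

#' @export
print.uelfa_confusion <- function(x, ...) {
  print(x$counts)
  cat(sprintf("overall accuracy: %.2f%%   macro recall: %.2f%%\n",
              100 * x$overall_accuracy, 100 * x$macro_recall))
  invisible(x)
}

#' Squared Pearson correlation of predicted vs true values
#'
#' The quantification metric for predicted-versus-true concentration. Being
#' a squared correlation it is sign-blind (`pred = -true` also gives 1);
#' goodness-of-fit of the baseline regressions uses the coefficient of
#' determination instead (see [baseline_euclidean_fit()]).
#'
#' @param pred,true Equal-length numeric vectors, n >= 2, neither constant.
#' @return Squared Pearson correlation in \[0, 1\].
#' @export
r_squared <- function(pred, true) {
  assert_that(length(pred) == length(true) && length(pred) >= 2,
              "need equal-length vectors with n >= 2")
  assert_that(stats::sd(pred) > 0 && stats::sd(true) > 0,
              "inputs must not be constant")
  stats::cor(pred, true)^2
}

#' Bland-Altman agreement analysis
#'
#' Differences `pred - true` summarised by their mean (bias), SD, and the
#' limits of agreement `bias +/- 1.96 * SD`; `fraction_within` counts
#' differences inside the limits, boundaries inclusive.
#'
#' @param pred,true Equal-length numeric vectors, n >= 3.
#' @return An object of class `uelfa_bland_altman`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `fraction_within`, `n`.
#' @export
bland_altman <- function(pred, true) {
  assert_that(length(pred) == length(true), "vectors must have equal length")
  assert_that(length(pred) >= 3, "Bland-Altman requires n >= 3")
  d <- pred - true
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa_low <- bias - 1.96 * sdd
  loa_high <- bias + 1.96 * sdd
  structure(
    list(bias = bias, sd_diff = sdd, loa_low = loa_low, loa_high = loa_high,
         fraction_within = mean(d >= loa_low & d <= loa_high),
         n = length(d)),
    class = "uelfa_bland_altman"
  )
}

#' @export
print.uelfa_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4g, LoA [%.4g, %.4g], %.1f%% within\n",
              x$n, x$bias, x$loa_low, x$loa_high, 100 * x$fraction_within))
  invisible(x)
}

#' IUPAC limit of detection
#'
#' `lod = blank_mean + 3 * blank_sd`, all in ng/mL; `lod_pg_ml` is the same
#' value in pg/mL. With the PBS blank background 0.0022 +/- 0.0021 ng/mL this
#' gives 8.50 pg/mL; with the serum background 0.0025 +/- 0.0026 ng/mL,
#' 10.30 pg/mL.
#'
#' @param blank_mean,blank_sd Blank background mean and SD (ng/mL),
#'   `blank_sd >= 0`.
#' @return A list: `blank_mean`, `blank_sd`, `lod` (ng/mL), `lod_pg_ml`.
#' @export
lod <- function(blank_mean, blank_sd) {
  assert_that(is_scalar_number(blank_sd) && blank_sd >= 0,
              "`blank_sd` must be >= 0")
  value <- blank_mean + 3 * blank_sd
  list(blank_mean = blank_mean, blank_sd = blank_sd, lod = value,
       lod_pg_ml = 1000 * value)
}

#' Colorimetric intensity of RGB records
#'
#' Normalised green-channel depletion
#' `(channel_base_G - G) / channel_gain_G`: red gold-nanoparticle bands
#' modulate green most strongly, so this is the scalar "colorimetric
#' intensity" used for the linear calibration and the specificity test.
#'
#' @param rgb Matrix/data.frame with columns `R`, `G`, `B` (or a named
#'   triple).
#' @param params An [assay_params()].
#' @return Numeric intensity vector.
#' @export
colorimetric_intensity <- function(rgb, params = assay_params()) {
  g <- if (is.data.frame(rgb) || is.matrix(rgb)) rgb[, "G"] else rgb[["G"]]
  (params$channel_base[["G"]] - as.numeric(g)) / params$channel_gain[["G"]]
}

#' Linear calibration over the linear dynamic range
#'
#' Ordinary least squares of colorimetric intensity on concentration,
#' restricted to samples inside the linear dynamic range (default
#' 0-0.4 ng/mL).
#'
#' @param conc Concentrations (ng/mL).
#' @param intensity Colorimetric intensities (see [colorimetric_intensity()]).
#' @param ldr Two-element range defining the LDR.
#' @return An object of class `uelfa_calibration`: `slope`, `intercept`,
#'   `r_squared` (coefficient of determination), `ldr`, `n`.
#' @export
linear_fit_ldr <- function(conc, intensity, ldr = c(0, 0.4)) {
  assert_that(length(conc) == length(intensity),
              "`conc` and `intensity` must align")
  sel <- conc >= ldr[1] & conc <= ldr[2]
  assert_that(sum(sel) >= 3, "need at least 3 points within the LDR")
  x <- conc[sel]
  y <- intensity[sel]
  assert_that(length(unique(x)) >= 2,
              "need at least 2 distinct concentrations within the LDR")
  fit <- stats::lm(y ~ x)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared, ldr = ldr, n = sum(sel)),
    class = "uelfa_calibration"
  )
}

#' @export
print.uelfa_calibration <- function(x, ...) {
  cat(sprintf("Linear calibration over [%g, %g] ng/mL (n = %d):\n",
              x$ldr[1], x$ldr[2], x$n))
  cat(sprintf("  intensity = %.5f * conc + %.5f   (R^2 = %.5f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

# Shared engine for the traditional single-feature baselines: simple linear
# regression of concentration on the feature; coefficient of determination.
baseline_fit <- function(feature, conc, feature_name) {
  fit <- stats::lm(conc ~ feature)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((conc - mean(conc))^2)
  assert_that(ss_tot > 0, "concentrations must not be constant")
  list(feature = feature_name, r_squared = 1 - ss_res / ss_tot,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(conc))
}

#' Traditional baseline fits
#'
#' The conventional strip-reader analyses the machine-learning workflow is
#' compared against: a simple linear regression of concentration on either
#' (a) the Euclidean distance of each RGB triple from the mean blank RGB
#' (`baseline_euclidean_fit()`), or (b) a single colour channel
#' (`baseline_channel_fit()`). Both report the coefficient of determination
#' `1 - SS_res / SS_tot`, which saturating high-concentration data drives
#' well below the cross-validated GPR R^2.
#'
#' @param rgb_records Matrix/data.frame with columns `R`, `G`, `B`.
#' @param conc Concentrations (ng/mL) aligned with the rows.
#' @return A list with `feature`, `r_squared`, `slope`, `intercept`, `n`.
#' @export
baseline_euclidean_fit <- function(rgb_records, conc) {
  rgb <- as.matrix(as.data.frame(rgb_records)[, c("R", "G", "B")])
  assert_that(nrow(rgb) == length(conc), "records and `conc` must align")
  blanks <- conc == 0
  assert_that(any(blanks),
              "no blank samples: the blank reference RGB is not computable")
  ref <- colMeans(rgb[blanks, , drop = FALSE])
  feature <- sqrt(colSums((t(rgb) - ref)^2))
  baseline_fit(feature, conc, "euclidean_distance")
}

#' @rdname baseline_euclidean_fit
#' @param channel One of `"R"`, `"G"`, `"B"`.
#' @export
baseline_channel_fit <- function(rgb_records, conc, channel = c("R", "G", "B")) {
  channel <- match.arg(channel)
  rgb <- as.data.frame(rgb_records)
  assert_that(nrow(rgb) == length(conc), "records and `conc` must align")
  baseline_fit(as.numeric(rgb[[channel]]), conc, channel)
}

#' Relative improvement percentage
#'
#' `(new - old) / old * 100`, the relative gain of the model metric over the
#' baseline metric.
#'
#' @param new,old Metric values; `old` must be non-zero.
#' @return Percentage.
#' @export
improvement_percent <- function(new, old) {
  assert_that(is_scalar_number(old) && old != 0, "`old` must be non-zero")
  (new - old) / old * 100
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-tailed p-value. Degenerate zero-variance cases are handled
#' deterministically: equal means give `t = 0, p = 1`; unequal means with
#' zero pooled variance give `t = +/-Inf, p = 0`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A list: `t`, `df`, `p`, the group means and sizes.
#' @export
welch_ttest <- function(group_a, group_b) {
  assert_that(length(group_a) >= 2 && length(group_b) >= 2,
              "each group needs n >= 2")
  na <- length(group_a); nb <- length(group_b)
  ma <- mean(group_a);   mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    t_stat <- if (ma == mb) 0 else sign(ma - mb) * Inf
    return(list(t = t_stat, df = na + nb - 2,
                p = if (ma == mb) 1 else 0,
                mean_a = ma, mean_b = mb, n_a = na, n_b = nb))
  }
  t_stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df),
       mean_a = ma, mean_b = mb, n_a = na, n_b = nb)
}

#' Clinical concentration-interval call
#'
#' Dichotomises predicted concentrations at a configured clinical cut-off:
#' `"positive"` iff `pred_conc >= threshold` (boundary equality is positive).
#' No default threshold ships with the package - the cut-off comes from the
#' clinical literature for the biomarker and population at hand and must be
#' supplied by the user.
#'
#' @param pred_conc Predicted concentration(s), ng/mL.
#' @param threshold Clinical decision threshold (ng/mL).
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
classify_clinical <- function(pred_conc, threshold) {
  if (missing(threshold) || is.null(threshold) || !is_scalar_number(threshold)) {
    stop("no clinical threshold configured: supply `threshold` (ng/mL), ",
         "e.g. via the `clinical.threshold_ng_ml` config key", call. = FALSE)
  }
  ifelse(pred_conc >= threshold, "positive", "negative")
}
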