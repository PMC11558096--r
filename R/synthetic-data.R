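# Synthetic assay data: dose-response, RGB record generator, blank statistics.
#
# Noise is injected in the concentration domain (the assay's blank background
# is reported in ng/mL), so the blank statistics are reproduced by
# construction; per-pixel RGB noise is added only at the rendering stage and
# averages out in ROI means.

#' Concentration ladder used throughout
#'
#' The nine-level tau calibration ladder (ng/mL) on which strips are prepared:
#' blank, then 0.02-4 ng/mL spanning two decades.
#' @export
tau_ladder <- c(0, 0.02, 0.04, 0.1, 0.2, 0.4, 1, 2, 4)

#' Assay generator parameters
#'
#' Parameters of the synthetic colorimetric response. The dose-response is a
#' saturating exponential whose initial slope equals `linear_slope` (the
#' fitted calibration slope on the 0-0.4 ng/mL linear dynamic range);
#' `response_scale` sets where saturation bends so the 1/2/4 ng/mL rungs stay
#' distinguishable. Blank noise is matrix specific: concentration-equivalent
#' background of 0.0022 +/- 0.0021 ng/mL in PBS and 0.0025 +/- 0.0026 ng/mL
#' in serum. Ultrasound enrichment multiplies the colorimetric signal
#' `enrichment_gain`-fold (default 10), capped so no channel leaves [0, 255].
#'
#' Channel gains convert normalised intensity to RGB depletion below the
#' unstained background `channel_base`; a red gold-nanoparticle band absorbs
#' green most strongly, so gain_G > gain_B > gain_R. The defaults (120/72/32
#' on base 235) keep the saturated depletion, `linear_slope * response_scale *
#' gain_G = 230.5`, inside the 8-bit range for the whole ladder.
#'
#' @param matrix `"PBS"` or `"serum"`; selects blank-noise defaults.
#' @param linear_slope Initial dose-response slope (intensity per ng/mL).
#' @param response_scale Saturation scale K_sat (ng/mL).
#' @param blank_mean_conc,blank_sd_conc Blank background mean/SD (ng/mL);
#'   defaults depend on `matrix`.
#' @param enrichment_gain Signal gain from ultrasound enrichment.
#' @param channel_base RGB triple of the unstained membrane.
#' @param channel_gain RGB depletion per unit intensity, named `R`, `G`, `B`.
#' @param lowend_noise_inflation Multiplier on `blank_sd_conc` for non-blank
#'   levels below 0.04 ng/mL; > 1 in serum-like matrices reproduces the
#'   0 vs 0.02 ng/mL confusion seen there.
#' @return An object of class `uelfa_assay_params`.
#' @export
assay_params <- function(matrix = c("PBS", "serum"),
                         linear_slope = 0.96041,
                         response_scale = 2,
                         blank_mean_conc = NULL,
                         blank_sd_conc = NULL,
                         enrichment_gain = 10,
                         channel_base = c(R = 235, G = 235, B = 235),
                         channel_gain = c(R = 32, G = 120, B = 72),
                         lowend_noise_inflation = NULL) {
  matrix <- match.arg(matrix)
  if (is.null(blank_mean_conc)) {
    blank_mean_conc <- if (matrix == "PBS") 0.0022 else 0.0025
  }
  if (is.null(blank_sd_conc)) {
    blank_sd_conc <- if (matrix == "PBS") 0.0021 else 0.0026
  }
  if (is.null(lowend_noise_inflation)) {
    lowend_noise_inflation <- if (matrix == "PBS") 1 else 1.25
  }
  assert_that(linear_slope > 0 && response_scale > 0 && enrichment_gain > 0,
              "slopes, scales and gains must be > 0")
  assert_that(blank_sd_conc >= 0, "`blank_sd_conc` must be >= 0")
  assert_that(lowend_noise_inflation > 0,
              "`lowend_noise_inflation` must be > 0")
  channel_base <- rgb_triple(channel_base)
  channel_gain <- rgb_triple(channel_gain)
  assert_that(all(channel_gain > 0), "channel gains must be > 0")
  assert_that(all(channel_base >= 0 & channel_base <= 255),
              "`channel_base` must map into [0, 255]")
  structure(
    list(matrix = matrix, linear_slope = linear_slope,
         response_scale = response_scale,
         blank_mean_conc = blank_mean_conc, blank_sd_conc = blank_sd_conc,
         enrichment_gain = enrichment_gain, channel_base = channel_base,
         channel_gain = channel_gain,
         lowend_noise_inflation = lowend_noise_inflation),
    class = "uelfa_assay_params"
  )
}

# Coerce a length-3 vector to named R/G/B order.
rgb_triple <- function(x) {
  assert_that(is.numeric(x) && length(x) == 3, "RGB values must be length 3")
  if (!is.null(names(x)) && setequal(names(x), c("R", "G", "B"))) {
    x <- x[c("R", "G", "B")]
  } else {
    names(x) <- c("R", "G", "B")
  }
  x
}

#' Saturating dose-response
#'
#' Normalised colorimetric intensity as a function of analyte concentration:
#' \deqn{I(c) = s\,K\,(1 - e^{-c/K})}
#' with initial slope `s = linear_slope` and saturation scale
#' `K = response_scale`. Strictly increasing, `I(0) = 0`, `I'(0) = s`, and
#' within 10% of the straight line `s c` over the 0-0.4 ng/mL linear dynamic
#' range at the defaults. For negative concentration-equivalent signal
#' (optical background fluctuating brighter than its mean) the curve is
#' extended linearly: `I(c) = s c` for `c < 0`.
#'
#' @param conc Concentration(s), ng/mL.
#' @param params An [assay_params()] object.
#' @return Normalised intensity, same length as `conc`.
#' @export
dose_response <- function(conc, params = assay_params()) {
  s <- params$linear_slope
  K <- params$response_scale
  ifelse(conc < 0, s * conc, s * K * (1 - exp(-conc / K)))
}

#' @rdname dose_response
#' @param intensity Normalised intensity to invert; must be below the
#'   saturation asymptote `linear_slope * response_scale`.
#' @export
inverse_dose_response <- function(intensity, params = assay_params()) {
  s <- params$linear_slope
  K <- params$response_scale
  assert_that(all(intensity < s * K),
              "intensity at or above the saturation asymptote is not invertible")
  ifelse(intensity < 0, intensity / s, -K * log(1 - intensity / (s * K)))
}

# SD inflation as a function of the nominal level: the low-end (non-blank,
# < 0.04 ng/mL) levels carry the matrix-interference multiplier.
noise_inflation <- function(conc, params) {
  ifelse(conc > 0 & conc < 0.04, params$lowend_noise_inflation, 1)
}

# Map per-record signal intensity to an RGB matrix (records x 3), applying
# the enrichment cap and the underflow guard.
intensity_to_rgb <- function(intensity, enriched, params, level_for_error) {
  gain <- if (enriched) params$enrichment_gain else 1
  signal <- intensity * gain
  if (enriched) {
    # enrichment gain is capped so the most-depleted channel floors at 0
    s_max <- min(params$channel_base / params$channel_gain)
    signal <- pmin(signal, s_max)
  }
  rgb <- t(params$channel_base - outer(params$channel_gain, signal))
  colnames(rgb) <- c("R", "G", "B")
  bad <- rowSums(rgb < 0 | rgb > 255) > 0
  if (any(bad)) {
    stop("channel underflow/overflow at level(s) ",
         paste(sort(unique(level_for_error[bad])), collapse = ", "),
         " ng/mL: channel gains too large for the requested intensities",
         call. = FALSE)
  }
  rgb
}

#' Generate a synthetic RGB dataset
#'
#' Draws `n_per_level` replicate strips at each ladder level. Each replicate
#' receives a concentration-domain perturbation
#' `eps ~ N(blank_mean_conc * 1{c = 0}, blank_sd_conc * inflation(c))`
#' (blanks sit on the optical background; non-blank low-end levels may carry
#' inflated matrix noise), is pushed through the dose-response, multiplied by
#' the enrichment gain when `enriched` (capped so channels stay in [0, 255]),
#' and converted to a real-valued RGB triple
#' `rgb = channel_base - channel_gain * signal`. Everything is reproducible
#' from `seed`.
#'
#' @param levels Concentration levels (ng/mL); default [tau_ladder].
#' @param n_per_level Replicates per level (>= 1).
#' @param matrix Sample matrix label, `"PBS"`, `"serum"` or `"plasma"`.
#' @param enriched Apply the ultrasound enrichment gain?
#' @param params An [assay_params()]; defaults to matrix-specific parameters
#'   (plasma uses the serum noise profile).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `sample_id`, `matrix`, `analyte`,
#'   `true_conc_ng_ml`, `enriched`, `R`, `G`, `B`, `class_label` (1-based
#'   index on the sorted ladder) and `qc_pass`.
#' @export
generate_dataset <- function(levels = tau_ladder, n_per_level = 15,
                             matrix = "PBS", enriched = FALSE,
                             params = NULL, seed = NULL) {
  assert_that(is.numeric(levels) && length(levels) >= 1 && all(levels >= 0),
              "`levels` must be non-negative concentrations")
  assert_that(is_scalar_number(n_per_level) && n_per_level >= 1,
              "`n_per_level` must be >= 1")
  if (is.null(params)) {
    params <- assay_params(if (matrix == "PBS") "PBS" else "serum")
  }
  sorted <- sort(unique(levels))
  with_seed(seed, {
    recs <- lapply(levels, function(cc) {
      eps <- rnorm(n_per_level,
                   mean = if (cc == 0) params$blank_mean_conc else 0,
                   sd = params$blank_sd_conc * noise_inflation(cc, params))
      c_eff <- cc + eps     # signed: background can fluctuate below zero
      rgb <- intensity_to_rgb(dose_response(c_eff, params), enriched, params,
                              rep(cc, n_per_level))
      data.frame(
        matrix = matrix,
        analyte = if (cc == 0) "blank" else "tau",
        true_conc_ng_ml = cc,
        enriched = enriched,
        R = rgb[, "R"], G = rgb[, "G"], B = rgb[, "B"],
        class_label = match(cc, sorted),
        qc_pass = TRUE
      )
    })
    out <- do.call(rbind, recs)
    out <- cbind(sample_id = sprintf("S%04d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}

#' Generate non-target (specificity) records
#'
#' Strips challenged with a non-target amyloid peptide instead of tau carry
#' blank-level optical background only: the sandwich pair does not bind the
#' non-target, so no dose-dependent signal forms.
#'
#' @param analyte `"Abeta40"` or `"Abeta42"`.
#' @param n Number of replicates (>= 1).
#' @inheritParams generate_dataset
#' @return A `data.frame` with the dataset schema of [generate_dataset()];
#'   `true_conc_ng_ml` records the challenge concentration but the signal is
#'   blank-level.
#' @export
generate_nontarget <- function(analyte = c("Abeta40", "Abeta42"), n = 10,
                               matrix = "PBS", params = NULL, seed = NULL) {
  analyte <- match.arg(analyte)
  assert_that(is_scalar_number(n) && n >= 1, "`n` must be >= 1")
  if (is.null(params)) {
    params <- assay_params(if (matrix == "PBS") "PBS" else "serum")
  }
  with_seed(seed, {
    eps <- rnorm(n, mean = params$blank_mean_conc, sd = params$blank_sd_conc)
    rgb <- intensity_to_rgb(dose_response(eps, params), FALSE, params,
                            rep(0, n))
    data.frame(
      sample_id = sprintf("N%04d", seq_len(n)),
      matrix = matrix, analyte = analyte, true_conc_ng_ml = 0,
      enriched = FALSE,
      R = rgb[, "R"], G = rgb[, "G"], B = rgb[, "B"],
      class_label = 1L, qc_pass = TRUE
    )
  })
}

#' Inverse calibration from generator parameters
#'
#' Returns a function mapping an RGB matrix (columns `R`, `G`, `B`) back to
#' concentration-equivalent signal (ng/mL) by inverting the green-channel
#' depletion through the dose-response. This is the generator's exact inverse
#' for unenriched records.
#'
#' @param params An [assay_params()].
#' @return `function(rgb) -> numeric` concentrations.
#' @export
make_inverse_calibration <- function(params = assay_params()) {
  force(params)
  function(rgb) {
    g <- if (is.data.frame(rgb) || is.matrix(rgb)) rgb[, "G"] else rgb["G"]
    intensity <- (params$channel_base[["G"]] - as.numeric(g)) /
      params$channel_gain[["G"]]
    inverse_dose_response(intensity, params)
  }
}

#' Blank background statistics
#'
#' Back-calculates each blank record through an inverse calibration and
#' returns the sample mean and SD of the concentration-equivalent background
#' - the two numbers entering the IUPAC blank + 3 SD detection limit.
#'
#' @param records Dataset rows with `true_conc_ng_ml == 0` (blanks); at least
#'   two are required.
#' @param calibration A function RGB-matrix -> concentration, e.g.
#'   [make_inverse_calibration()].
#' @return A list with `mean` and `sd` (ng/mL) and `n`.
#' @export
blank_statistics <- function(records, calibration = make_inverse_calibration()) {
  blanks <- records[records$true_conc_ng_ml == 0, , drop = FALSE]
  if (nrow(blanks) < 2) {
    stop("at least 2 blank records are required", call. = FALSE)
  }
  conc <- calibration(blanks[, c("R", "G", "B")])
  list(mean = mean(conc), sd = stats::sd(conc), n = nrow(blanks))
}

#' Noise-free detectability threshold on a concentration ladder
#'
#' Smallest ladder level whose noise-free colorimetric signal (after any
#' enrichment gain) reaches the visual-detectability intensity. With the
#' default gain of 10 the threshold moves one decade down the ladder
#' (0.2 -> 0.02 ng/mL): in the linear regime a 10-fold signal gain is
#' equivalent to a 10-fold concentration gain.
#'
#' @param params An [assay_params()].
#' @param enriched Apply the enrichment gain?
#' @param levels Ladder to scan; default [tau_ladder].
#' @param visual_threshold Intensity deemed visible by eye; the default 0.15
#'   lies between the noise-free intensities of the 0.1 and 0.2 ng/mL rungs.
#' @return The smallest detectable level (ng/mL), or `NA` if none.
#' @export
detectability_threshold <- function(params = assay_params(), enriched = FALSE,
                                    levels = tau_ladder,
                                    visual_threshold = 0.15) {
  gain <- if (enriched) params$enrichment_gain else 1
  lv <- sort(levels[levels > 0])
  vis <- dose_response(lv, params) * gain >= visual_threshold
  if (!any(vis)) NA_real_ else lv[which(vis)[1]]
}

#' Read / write the dataset CSV schema
#'
#' Plain CSV with columns `sample_id`, `matrix`, `analyte`,
#' `true_conc_ng_ml`, `enriched`, `R`, `G`, `B`, `class_label`, `qc_pass`.
#'
#' @param data Dataset `data.frame`.
#' @param path File path.
#' @return `read_dataset()`: the `data.frame`; `write_dataset()`: `path`,
#'   invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "true_conc_ng_ml", "R", "G", "B", "class_label",
              "qc_pass")
  missing <- setdiff(needed, names(out))
  assert_that(length(missing) == 0,
              paste("dataset is missing columns:", paste(missing, collapse = ", ")))
  out
}
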