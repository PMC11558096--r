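# Synthetic strip rendering. Images are h x w x 3 real-valued arrays in
# [0, 255]; rows run across the strip width, columns along the flow axis.
# Bands have a flat core (the ground-truth ROI, whose mean colour equals the
# record's RGB exactly at zero pixel noise) with Gaussian shoulders.

#' Strip geometry
#'
#' Physical layout of a rendered strip: a 4 mm wide membrane with the control
#' line 7 mm downstream of the test line.
#'
#' @param length_mm Strip length along the flow axis.
#' @param width_mm Strip width; assay strips are cut to 4 mm.
#' @param mm_per_px Pixel pitch of the rendering/extraction.
#' @param control_pos_mm Centre of the control band from the strip start.
#' @param line_separation_mm Control-to-test band separation (7 mm).
#' @param band_halfwidth_mm Half-width of the flat band core.
#' @param band_edge_sd_mm Gaussian SD of the band shoulders.
#' @return An object of class `uelfa_geometry`.
#' @export
strip_geometry <- function(length_mm = 25, width_mm = 4, mm_per_px = 0.1,
                           control_pos_mm = 15, line_separation_mm = 7,
                           band_halfwidth_mm = 0.4, band_edge_sd_mm = 0.15) {
  g <- list(length_mm = length_mm, width_mm = width_mm, mm_per_px = mm_per_px,
            control_pos_mm = control_pos_mm,
            line_separation_mm = line_separation_mm,
            band_halfwidth_mm = band_halfwidth_mm,
            band_edge_sd_mm = band_edge_sd_mm)
  assert_that(all(vapply(g, is_scalar_number, logical(1))) &&
                all(unlist(g) > 0), "geometry fields must be positive numbers")
  assert_that(control_pos_mm < length_mm &&
                control_pos_mm - line_separation_mm > 0,
              "band centres must lie inside the strip")
  structure(g, class = "uelfa_geometry")
}

# Column-weight profile of one band: 1 on the flat core, Gaussian shoulders.
band_weights <- function(pos_mm, center_mm, halfwidth_mm, edge_sd_mm) {
  d <- abs(pos_mm - center_mm)
  w <- numeric(length(d))
  core <- d <= halfwidth_mm
  w[core] <- 1
  w[!core] <- exp(-((d[!core] - halfwidth_mm)^2) / (2 * edge_sd_mm^2))
  w
}

# Columns (1-based, inclusive) of a band's flat core.
band_core_cols <- function(pos_mm, center_mm, halfwidth_mm) {
  range(which(abs(pos_mm - center_mm) <= halfwidth_mm))
}

#' Render a strip photograph from a sample record
#'
#' Draws the membrane background at `channel_base`, a control band (always,
#' unless `control_line_present = FALSE`) and a test band whose flat-core
#' colour equals the record's RGB, then adds iid per-pixel Gaussian noise and
#' clips to \[0, 255\].
#'
#' @param record One dataset row (or list) with `R`, `G`, `B` components.
#' @param geometry A [strip_geometry()].
#' @param params An [assay_params()] supplying the background colour and the
#'   control-band colour (unit-intensity depletion).
#' @param pixel_noise_sd SD of the per-pixel noise (8-bit units).
#' @param seed Integer seed for the pixel noise.
#' @param control_line_present Draw the control band? Invalid runs
#'   (exhausted conjugate, failed wicking) lack it.
#' @return An object of class `uelfa_strip`: `pixels` (h x w x 3 array),
#'   geometry metadata and `ground_truth_rois` (column ranges of the band
#'   cores).
#' @export
render_strip <- function(record, geometry = strip_geometry(),
                         params = assay_params(), pixel_noise_sd = 0,
                         seed = NULL, control_line_present = TRUE) {
  test_rgb <- c(R = as.numeric(record$R), G = as.numeric(record$G),
                B = as.numeric(record$B))
  assert_that(all(is.finite(test_rgb)) && all(test_rgb >= 0 & test_rgb <= 255),
              "record RGB must lie in [0, 255]")
  assert_that(pixel_noise_sd >= 0, "`pixel_noise_sd` must be >= 0")

  n_cols <- round(geometry$length_mm / geometry$mm_per_px)
  n_rows <- round(geometry$width_mm / geometry$mm_per_px)
  pos_mm <- (seq_len(n_cols) - 0.5) * geometry$mm_per_px
  control_mm <- geometry$control_pos_mm
  test_mm <- geometry$control_pos_mm - geometry$line_separation_mm
  margin <- geometry$band_halfwidth_mm + 3 * geometry$band_edge_sd_mm
  if (test_mm - margin < 0 || control_mm + margin > geometry$length_mm) {
    stop("bands fall outside the strip image; enlarge the strip or move the ",
         "control position", call. = FALSE)
  }

  control_rgb <- params$channel_base - params$channel_gain * 1
  w_test <- band_weights(pos_mm, test_mm, geometry$band_halfwidth_mm,
                         geometry$band_edge_sd_mm)
  w_ctrl <- if (control_line_present) {
    band_weights(pos_mm, control_mm, geometry$band_halfwidth_mm,
                 geometry$band_edge_sd_mm)
  } else numeric(n_cols)

  pixels <- array(0, dim = c(n_rows, n_cols, 3),
                  dimnames = list(NULL, NULL, c("R", "G", "B")))
  for (ch in 1:3) {
    base <- params$channel_base[[ch]]
    col_profile <- base + (test_rgb[[ch]] - base) * w_test +
      (control_rgb[[ch]] - base) * w_ctrl
    pixels[, , ch] <- matrix(col_profile, nrow = n_rows, ncol = n_cols,
                             byrow = TRUE)
  }
  if (pixel_noise_sd > 0) {
    with_seed(seed, {
      pixels <- pixels + array(rnorm(length(pixels), 0, pixel_noise_sd),
                               dim = dim(pixels))
    })
    pixels <- pmin(pmax(pixels, 0), 255)
  }

  structure(
    list(pixels = pixels, mm_per_px = geometry$mm_per_px,
         strip_width_mm = geometry$width_mm,
         line_separation_mm = geometry$line_separation_mm,
         control_line_present = control_line_present,
         ground_truth_rois = list(
           test = band_core_cols(pos_mm, test_mm, geometry$band_halfwidth_mm),
           control = if (control_line_present) {
             band_core_cols(pos_mm, control_mm, geometry$band_halfwidth_mm)
           } else NULL
         ),
         geometry = geometry),
    class = "uelfa_strip"
  )
}

#' @export
print.uelfa_strip <- function(x, ...) {
  d <- dim(x$pixels)
  cat("LFA strip image:", d[1], "x", d[2], "px (",
      x$strip_width_mm, "x", d[2] * x$mm_per_px, "mm ),",
      if (x$control_line_present) "control line present" else "NO control line",
      "\n")
  invisible(x)
}

#' Plain-text strip image I/O
#'
#' Serialises a strip as a long-format CSV (`row`, `col`, `R`, `G`, `B`) with
#' a JSON sidecar carrying the geometry metadata and ground-truth ROIs, and
#' reads the pair back. Used by the command-line interface; binary image
#' formats are deliberately avoided.
#'
#' @param image A `uelfa_strip`.
#' @param csv_path Pixel CSV path; the sidecar is written next to it as
#'   `<csv_path>.json`.
#' @return `write_strip_csv()`: `csv_path` invisibly; `read_strip_csv()`: the
#'   `uelfa_strip`.
#' @export
write_strip_csv <- function(image, csv_path) {
  d <- dim(image$pixels)
  tab <- data.frame(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    R = as.vector(image$pixels[, , "R"]),
    G = as.vector(image$pixels[, , "G"]),
    B = as.vector(image$pixels[, , "B"])
  )
  utils::write.csv(tab, csv_path, row.names = FALSE)
  meta <- image[setdiff(names(image), "pixels")]
  meta$geometry <- unclass(meta$geometry)
  jsonlite::write_json(meta, paste0(csv_path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(csv_path)
}

#' @rdname write_strip_csv
#' @export
read_strip_csv <- function(csv_path) {
  tab <- utils::read.csv(csv_path)
  meta <- jsonlite::read_json(paste0(csv_path, ".json"), simplifyVector = TRUE)
  n_rows <- max(tab$row)
  n_cols <- max(tab$col)
  ord <- order(tab$col, tab$row)
  pixels <- array(0, dim = c(n_rows, n_cols, 3),
                  dimnames = list(NULL, NULL, c("R", "G", "B")))
  for (ch in c("R", "G", "B")) {
    pixels[, , ch] <- matrix(tab[[ch]][ord], nrow = n_rows, ncol = n_cols)
  }
  meta$geometry <- do.call(strip_geometry, as.list(meta$geometry))
  rois <- meta$ground_truth_rois
  structure(
    c(list(pixels = pixels), meta[setdiff(names(meta), "ground_truth_rois")],
      list(ground_truth_rois = rois)),
    class = "uelfa_strip"
  )
}
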