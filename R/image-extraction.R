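# Line detection, test-line RGB extraction and the control-line QC filter.

#' Longitudinal colour profile of a strip
#'
#' Averages each channel across the strip width, giving one mean RGB triple
#' per column along the flow axis.
#'
#' @param image A `uelfa_strip` (see [render_strip()]).
#' @return An object of class `uelfa_profile`: `positions` (mm, strictly
#'   increasing, one per column) and `mean_rgb` (n_cols x 3 matrix).
#' @export
longitudinal_profile <- function(image) {
  d <- dim(image$pixels)
  assert_that(!is.null(d) && d[1] >= 1 && d[2] >= 1,
              "image must have at least one row and one column of pixels")
  mean_rgb <- sapply(c("R", "G", "B"), function(ch) {
    m <- image$pixels[, , ch, drop = FALSE]
    dim(m) <- d[1:2]
    colMeans(m)
  })
  if (is.null(dim(mean_rgb))) {
    mean_rgb <- matrix(mean_rgb, nrow = 1,
                       dimnames = list(NULL, c("R", "G", "B")))
  }
  structure(
    list(positions = (seq_len(d[2]) - 0.5) * image$mm_per_px,
         mean_rgb = mean_rgb, mm_per_px = image$mm_per_px),
    class = "uelfa_profile"
  )
}

# Contiguous runs of TRUE in a logical vector -> matrix of (start, end).
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Locate control and test bands on a profile
#'
#' Candidate bands are contiguous runs where the green channel drops below an
#' adaptive background (median of the profile) by more than a depth
#' threshold; green carries the deepest modulation of a red
#' gold-nanoparticle band. The control band is the candidate nearest the
#' expected control position, and the test band must sit
#' `line_separation_mm` upstream of the detected control within
#' `tolerance_mm`. Absence is reported through flags, never as an error: a
#' missing control line marks the run invalid (`qc_pass = FALSE`), and a
#' missing test band simply means blank-level signal.
#'
#' @param profile A [longitudinal_profile()].
#' @param geometry A [strip_geometry()].
#' @param tolerance_mm Allowed deviation of the test band from its expected
#'   position.
#' @param min_depth Floor (8-bit units) on the adaptive depth threshold
#'   `3 * mad(G)`; keeps shoulder pixels and faint noise out of the candidate
#'   set on noise-free images.
#' @return A list: `control_found`, `test_found`, `control_pos_mm`,
#'   `test_pos_mm` (NA when not found), `control_run`, `test_run` (column
#'   ranges) and `qc_pass` (= `control_found`).
#' @export
detect_lines <- function(profile, geometry = strip_geometry(),
                         tolerance_mm = 1, min_depth = 5) {
  g <- profile$mean_rgb[, "G"]
  background <- stats::median(g)
  depth_threshold <- max(3 * stats::mad(g), min_depth)
  cand <- runs_of(g < background - depth_threshold)

  out <- list(control_found = FALSE, test_found = FALSE,
              control_pos_mm = NA_real_, test_pos_mm = NA_real_,
              control_run = NULL, test_run = NULL, qc_pass = FALSE)
  if (nrow(cand) == 0) return(out)

  centers <- (profile$positions[cand[, "start"]] +
                profile$positions[cand[, "end"]]) / 2
  i_ctrl <- which.min(abs(centers - geometry$control_pos_mm))
  # the control line must be near where the dispenser put it
  if (abs(centers[i_ctrl] - geometry$control_pos_mm) <= tolerance_mm) {
    out$control_found <- TRUE
    out$control_pos_mm <- centers[i_ctrl]
    out$control_run <- unname(cand[i_ctrl, ])
    out$qc_pass <- TRUE
    expected_test <- out$control_pos_mm - geometry$line_separation_mm
    rest <- setdiff(seq_len(nrow(cand)), i_ctrl)
    if (length(rest) > 0) {
      i_test <- rest[which.min(abs(centers[rest] - expected_test))]
      if (abs(centers[i_test] - expected_test) <= tolerance_mm) {
        out$test_found <- TRUE
        out$test_pos_mm <- centers[i_test]
        out$test_run <- unname(cand[i_test, ])
      }
    }
  }
  out
}

#' Mean RGB over a region of interest
#'
#' Arithmetic mean of all pixels in the column range `roi` (full strip
#' width), one real value per channel.
#'
#' @param image A `uelfa_strip`.
#' @param roi Integer `c(first_col, last_col)`, 1-based inclusive.
#' @return Named numeric triple `R`, `G`, `B`.
#' @export
extract_rgb <- function(image, roi) {
  d <- dim(image$pixels)
  assert_that(length(roi) == 2 && roi[1] >= 1 && roi[2] <= d[2] &&
                roi[1] <= roi[2], "`roi` must be a non-empty column range inside the image")
  cols <- seq.int(roi[1], roi[2])
  vapply(c("R", "G", "B"),
         function(ch) mean(image$pixels[, cols, ch]), numeric(1))
}

#' Full extraction of one strip
#'
#' Profiles the image, detects the bands, and averages the test-line ROI: a
#' window centred on the detected band (midpoint of the threshold run),
#' shrunk two pixels inside the nominal band half-width so edge gradients
#' never enter the mean - at zero pixel noise the ROI mean therefore equals
#' the record's RGB exactly. When the control line is found but the test
#' band is too faint to detect, the ROI falls back to the expected window
#' `line_separation_mm` upstream of the detected control, so blank-level
#' strips still yield an RGB record.
#'
#' @inheritParams detect_lines
#' @param image A `uelfa_strip`.
#' @return A list (`uelfa_extraction`): detection flags and positions,
#'   `test_roi`, `mean_rgb`, `qc_pass`.
#' @export
extract_strip <- function(image, geometry = strip_geometry(),
                          tolerance_mm = 1, min_depth = 5) {
  det <- detect_lines(longitudinal_profile(image), geometry, tolerance_mm,
                      min_depth)
  roi <- NULL
  n_cols <- dim(image$pixels)[2]
  half_px <- max(1L, floor(geometry$band_halfwidth_mm / image$mm_per_px) - 2L)
  center_px <- if (det$test_found) {
    round(mean(det$test_run))
  } else if (det$control_found) {
    round((det$control_pos_mm - geometry$line_separation_mm) / image$mm_per_px)
  } else NULL
  if (!is.null(center_px)) {
    roi <- c(max(1L, center_px - half_px), min(n_cols, center_px + half_px))
  }
  structure(
    c(det[c("control_found", "test_found", "control_pos_mm", "test_pos_mm",
            "qc_pass")],
      list(test_roi = roi,
           mean_rgb = if (is.null(roi)) {
             c(R = NA_real_, G = NA_real_, B = NA_real_)
           } else {
             extract_rgb(image, roi)
           })),
    class = "uelfa_extraction"
  )
}

#' Control-line validity filter
#'
#' Retains exactly the records whose control line was found: assay validity
#' is defined by the control line, so strips without one are discarded
#' before any modelling.
#'
#' @param results A list of `uelfa_extraction` objects, or a `data.frame`
#'   with a logical `qc_pass` column.
#' @return The retained subset, same type as the input.
#' @export
qc_filter <- function(results) {
  if (is.data.frame(results)) {
    results[as.logical(results$qc_pass), , drop = FALSE]
  } else {
    Filter(function(r) isTRUE(r$qc_pass), results)
  }
}
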