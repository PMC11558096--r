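Package: uelfa
Title: Ultrasound-Enriched Lateral Flow Assay Simulation and Colorimetric Quantification
Version: 1.0.0
Authors@R:
    person("UELFA", "Developers", email = "uelfa@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing ultrasound-enriched colorimetric
    lateral flow assays (LFA). Implements the primary acoustic radiation force on
    particles in a one-dimensional standing-wave cavity and an overdamped
    particle-migration simulator demonstrating pressure-node aggregation; a
    synthetic strip and RGB dataset generator with a saturating dose-response,
    concentration-domain blank noise and configurable enrichment gain; strip-image
    line detection, test-line RGB extraction and control-line quality filtering;
    k-nearest-neighbour classification and Gaussian process regression calibration
    with stratified k-fold cross-validation; and the downstream evaluation layer:
    confusion matrices, R-squared, Bland-Altman agreement, linear calibration with
    an IUPAC blank + 3 SD limit of detection, baseline single-channel and
    Euclidean-distance fits, Welch's t-test and clinical concentration-interval
    calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
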