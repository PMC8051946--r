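Package: poltune
Title: Polarization-Tuning Analysis for Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for polarization-tuning experiments recorded
    with two-channel volumetric two-photon calcium imaging under a stepped
    rotating-polarizer stimulus. Provides a synthetic-data generator with
    known ground truth, subpixel rigid registration on an activity-independent
    structural channel, inactivity-based maximum-intensity projections,
    per-pixel and per-ROI axial (180-degree periodic) tuning curves, preferred
    angle of polarization and polarization-selectivity index (PSI) estimation,
    automatic tuning-based ROI generation, circular-linear polarotopy
    regression with permutation testing and hierarchical bootstrap confidence
    intervals, PSI-weighted population tuning vectors, area-true polar
    histograms, and protocerebral-bridge glomerulus analyses (left/right
    pairing by cross-correlation, auto-correlation phase locking, and
    cycle-by-cycle tuning shifts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
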