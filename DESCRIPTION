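Package: pulsemap
Title: Full-Field Microvascular Pulsatility Mapping from Laser Speckle and
    Two-Photon Line-Scan Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify cardiac-cycle-resolved blood flow and vessel
    diameter pulsatility in the cerebral microvasculature. Converts
    high-frame-rate laser speckle contrast imaging (LSCI) recordings to
    spatial contrast and blood flow index (BFI = 1/K^2), detects and
    quality-screens individual cardiac cycles from the whole-field contrast
    time course, ensemble-averages them into a representative cardiac cycle
    with temporal super-resolution, and derives per-pixel and per-vessel
    pulsatility indexes (PI = (max - min)/mean) for flow and diameter via
    dynamic sub-pixel vessel segmentation. Capillary diameter and wall
    displacement pulsatility are quantified from two-photon cross-sectional
    line scans using per-column k-means segmentation, gapped time-series
    extraction, windowed Lomb-Scargle periodograms, and cardiac-band
    peak-prominence signal-to-noise ratios. A synthetic-data module generates
    ground-truthed speckle videos and line-scan phantoms so that every
    pipeline stage is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
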