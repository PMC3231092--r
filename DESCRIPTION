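Package: cawall
Title: Carotid Artery Wall Boundary Detection in Dynamic B-Mode Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated detection of the intima and adventitia of both the near
    and far walls of the common carotid artery in dynamic B-mode image
    sequences. Boundary evidence is built from a bank of oriented MacLeod
    edge filters plus wall-specific enhancement kernels; the two wall
    interfaces are extracted jointly by a constrained dual
    dynamic-programming optimizer (non-crossing, thickness-bounded, smooth
    curves with exact backtracking), the region of interest is re-registered
    across frames by normalized cross-correlation tracking, and per-frame
    lumen-diameter series are assembled from the detected intima lines.
    Includes a synthetic pulsatile artery phantom with exact sub-pixel
    ground truth, speckle noise, wall drift, plaque bumps and a sub-intima
    noise layer, plus error metrics (per-frame unsigned/signed boundary
    error, pixel-to-millimetre conversion, distensibility and stiffness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
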