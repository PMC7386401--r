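Package: photoscreen
Title: Smartphone Photoscreening Analysis for Pediatric Vision Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses paired smartphone photoscreening images (a flash still
    for the automated Hirschberg test and a maximally exposed frame for red
    reflex photorefraction) to measure binocular visual-axis deviation, red
    reflex crescent widths and interpupillary distance, and to flag risk of
    strabismus, myopia and anisometropia in children. Includes arc-restricted
    circle Hough limbus detection, IsoData thresholding, corneal reflection
    and crescent extraction, fiducial-based pixel-to-millimetre calibration,
    a batch screening pipeline with evaluation metrics, and a synthetic
    eye-scene renderer that provides exact ground truth so the whole pipeline
    can be validated without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
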