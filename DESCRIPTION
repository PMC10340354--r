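Package: flexbeam
Title: Shape Estimation and Delay-and-Sum Beamforming for Flexible
    Ultrasound Array Transducers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for imaging with flexible ultrasound array transducers,
    whose element positions are unknown at acquisition time. Implements
    optical-marker-based array shape estimation (PCA projection, Pratt
    least-squares circle fitting, radius correction), an entropy-maximizing
    shape optimization over an external-angle polyline model, time-of-flight
    delay-and-sum beamforming with nearest-sample extraction, B-mode scan
    conversion with bilinear interpolation and region masking, and an
    image-quality evaluation suite (lateral FWHM, aspect ratio, Dice,
    Jaccard, Hausdorff with rigid pre-registration, CNR, GCNR). A built-in
    synthetic RF channel-data simulator with point targets, speckle
    backgrounds, and elliptical inclusions makes the full pipeline testable
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
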