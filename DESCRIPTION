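Package: whisker3d
Title: Automatic 3D Whisker Tracking from Stereo High-Speed Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tracks the basal segments of rodent whiskers in three dimensions
    from paired horizontal/vertical high-speed video by fitting quadratic
    Bezier curves that minimise an image-evidence plus regularisation cost.
    Includes orthographic (telecentric) stereo calibration by linear
    regression, snout contour detection, a multi-whisker tracking loop with
    temporal and shape priors, and extraction of 3D kinematics (azimuth,
    elevation, roll) and 3D curvature with the bending-moment proxy
    delta-kappa-3D. A seeded synthetic stereo-scene generator produces
    whisking sequences, calibration pin sequences, and a rigid rotating-edge
    control with exact ground truth, so the whole pipeline can be validated
    offline without recorded video.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    png,
    optparse,
    pracma,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
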