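Package: herdtrack
Title: Multi-Object Tracking of Wildlife in Aerial Drone Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tracking-by-detection of animals (herding ungulates) in UAV
    video. Implements an 8-state constant-velocity Kalman tracker in the
    Deep SORT tradition, extended with camera motion compensation (horizon
    detection, static-region masking, FAST/BRIEF keypoint matching and
    RANSAC affine estimation applied to every track's state and
    covariance) and a confidence-tiered cascaded data association that
    recovers partially occluded, low-confidence detections. Also provides
    the CARAFE content-aware feature-reassembly upsampling operator as a
    standalone numeric primitive, CLEAR-MOT / IDF1 / average-precision
    evaluation, MOTChallenge-format readers and writers, and a seeded
    synthetic UAV-scenario simulator (curving trajectories, global camera
    jitter, occlusion episodes, appearance descriptors, rendered frames)
    used as the test substrate for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
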