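Package: usnav
Title: Tracked Freehand 3D Ultrasound Reconstruction, Rigid Registration,
    and Navigation System Accuracy Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of an image-guided-therapy navigation
    pipeline. Provides rigid-body transforms with checked coordinate-frame
    chains and quaternion pose interpolation; landmark (least-squares), fast
    single-landmark, centerline iterative-closest-point and
    trajectory-to-airway rigid registration; pixel-nearest-neighbour
    freehand 3D ultrasound reconstruction with probe-sector clipping and
    temporal calibration; an automatic wire-cross-phantom method for
    measuring navigation system accuracy (segmentation, 3D binary-thinning
    centerline extraction, modified ICP to a nominal model) with a
    root-sum-of-squares error-budget combiner; and a seeded phantom/sweep
    simulator with injectable calibration, jitter, sound-speed and latency
    errors. Readers and writers for MetaImage volumes, pose and landmark
    CSV, transform text files and tool-configuration XML, plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
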