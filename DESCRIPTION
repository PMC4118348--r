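Package: fallwatch
Title: Fall and Faint Detection in Video by Adaptive Background Modeling
    and Rule-Based Posture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, classifies and tracks moving human silhouettes in
    indoor video and raises fall/faint alarms from simple spatiotemporal
    rules. Implements per-pixel Gaussian-mixture background subtraction
    with dual luminance/chrominance models for cast-shadow elimination,
    morphological artifact removal and candidate-object extraction,
    HOG-descriptor template matching and a boosted Haar-feature cascade
    for human classification, Mean-Shift tracking with hue-histogram
    back-projection, and a posture state machine driven by bounding-box
    aspect ratio, area and centroid speed with a persistence requirement
    before the alarm fires. A deterministic synthetic-scene renderer
    produces frame sequences with ground truth so the whole pipeline is
    testable without video data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
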