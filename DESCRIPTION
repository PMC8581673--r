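Package: bhvtrack
Title: Hybrid Detector and Background-Subtraction Tracking for Laboratory
    Animal Behavior Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Centroid tracking of laboratory animals in behavior videos by
    combining a learned object detector (bounding-box proposals with
    confidence scores) with classical background subtraction restricted to
    the enlarged best-scoring box. Includes video/image-sequence ingestion
    at a fixed working resolution, tracking-area masking, keyframe
    extraction and dataset splitting for detector training, a compact
    trainable single-scale convolutional detector with oracle and blob mock
    backends, temporal-median background modelling with connected-component
    centroid extraction, whole-video tracking with manual correction and a
    feedback loop that collects failed frames for relabeling, trajectory
    kinematics, occupancy heat maps, region dwell times, error to ground
    truth, two-animal color-marker identity assignment, and a synthetic
    arena-video generator with exact ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    pracma,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
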