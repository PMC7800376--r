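Package: obstride
Title: Kinematic Analysis of Whisker-Guided Obstacle Avoidance in Running Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-speed pose-tracking data from head-fixed
    mice stepping over obstacles on a running wheel. Implements post-processing
    of markerless landmark tracking (confidence masking, de-spiking, cross-view
    consistency, interpolation, un-head-fixing), stance and step segmentation
    with Hildebrand gait diagrams, speed-based landing-position models, a
    class-weighted logistic model of the shorten-versus-lengthen step decision
    with cross-validation and greedy forward feature selection, matched-control
    reaction-time estimation, sliding-window consensus detection of whisker
    contact, matched-trial comparison for manipulation experiments, and a
    synthetic gait-and-decision simulator with planted ground truth that makes
    every pipeline stage testable without raw video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
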