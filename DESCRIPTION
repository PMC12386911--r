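Package: crownwatch
Title: Detection of Weakened and Dead Pine Crowns in UAV Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for single-stage detection of pine tree
    health decline in UAV RGB imagery. Implements strip (directional
    depthwise) convolution backbone blocks, channel-aware context attention
    for feature fusion, and the size-adaptive SDIoU bounding-box regression
    loss, together with an anchor-free detector, precision/recall/AP
    evaluation with all-points PR envelopes, LabelImg Pascal-VOC and YOLO
    annotation I/O, a ground-survey accuracy-rate validation procedure, and
    a seeded synthetic generator of orthophoto and oblique forest scenes
    with three crown health classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    png,
    yaml,
    xml2,
    jsonlite,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
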