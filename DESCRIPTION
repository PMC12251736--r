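Package: leafyolo
Title: Single-Stage Leaf-Disease Lesion Detection with Space-to-Depth
    Convolution and Parameter-Free Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting disease lesions on leaves photographed
    against cluttered natural backgrounds. Implements the IoU, CIoU and
    MPDIoU bounding-box regression losses in scalar and batched form; the
    SPD (space-to-depth) transform, SimAM parameter-free attention, the
    composite SSPDConv downsampling block and the ESPPFCSPC dilated
    cross-stage spatial-pyramid-pooling block; assembly of a YOLOv8n-style
    anchor-free single-stage detector with exact parameter and FLOP
    accounting, a CPU-scale training loop, and non-maximum-suppression
    inference. Also provides an image background-complexity classifier
    (colour-histogram entropy, dominant-colour proportion, edge density),
    a seeded synthetic leaf-scene generator with YOLO-format output and an
    augmentation suite, and detection evaluation (precision, recall,
    mAP at IoU 0.5, confusion matrix) with a TIDE-style error decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
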