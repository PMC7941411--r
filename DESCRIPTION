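Package: CobQuant
Title: Estimating Corn-Ear Consumption from Instance Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing and evaluation toolkit for estimating how much of
    a corn ear has been eaten from per-instance segmentation masks of
    feeding-stand photographs. Reads VGG Image Annotator (VIA) polygon
    annotations and external detection manifests, groups bare-cob (and kernel)
    instances to individual ears, computes per-ear consumption percentages and
    left-versus-right verdicts, and evaluates segmentation and estimation
    quality (weighted mean IoU, COCO-style mAP, precision-recall curves,
    R-squared with outlier exclusion, left-right confusion matrices, and a
    stratified sample-size ablation harness with Welch t-tests). A synthetic
    paired-ear scene generator with pixel-exact ground truth and a classical
    color/connected-component segmentation backend make the full pipeline
    testable without the original images or a trained network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
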