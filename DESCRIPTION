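Package: swnet
Title: Wide Multi-Branch Convolutional Networks for Skin Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and audits SWNet, a wide four-stage multi-branch
    convolutional neural network for benign/malignant dermoscopy image
    classification. Provides a directed-acyclic-graph network builder with
    structural and parameter audits, a CPU training loop (mini-batch SGD with
    momentum and batch normalization), confusion-matrix metrics, Grad-CAM
    saliency maps with region-mass statistics for bias auditing, multi-dataset
    deep feature fusion, and a synthetic dermoscopy image generator with
    controllable lesion morphology and confounding artifacts (circular
    vignette, hair) so the whole pipeline can be exercised without any
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    glmnet,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jpeg,
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
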