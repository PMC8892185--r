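Package: noduleseg
Title: Three-Dimensional Lung Nodule Segmentation with Nested Residual
    Networks and Classical Baselines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for volumetric segmentation of lung nodules in CT-like
    images. Provides a nested residual 3D fully-convolutional network with
    deep supervision trained with a lambda-weighted combination of binary
    cross-entropy and Dice loss, plus 3D U-Net and 3D SegNet baselines, all
    built on a self-contained reverse-mode differentiation engine with
    compiled convolution kernels. Classical marker-based watershed and
    graph-cut segmenters, a parametric CT nodule phantom generator with
    ground-truth masks, NIfTI volume input/output, a 96-variant
    rotation/mirroring augmentation scheme, Dice/IoU evaluation with k-fold
    cross-validation, and a command-line interface are included.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
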