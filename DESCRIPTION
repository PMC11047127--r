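Package: afmsnet
Title: Adaptive Attention Encoder-Decoder Networks for 3D Brain Lesion
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric (3D) semantic segmentation of brain lesions with
    attention-augmented encoder-decoder networks. Provides two encoder blocks
    - a squeeze-and-excitation channel-attention block (SAEB) and a dual
    channel-plus-spatial attention block (DAEB) - together with an iterative
    skip-connection refinement path (SegPath), a combined Dice and categorical
    focal loss, and an evaluation suite including the average Hausdorff
    distance. All tensor operations (3D convolution, transpose convolution,
    max pooling, batch normalization) are implemented natively with
    reverse-mode automatic differentiation, so networks train on the CPU
    without an external deep-learning framework. Includes NIfTI volume I/O and
    preprocessing transforms (central crop, resampling, z-score
    normalization, Gaussian smoothing, one-hot encoding, modality fusion),
    a seeded synthetic lesion-phantom generator with nested multi-class
    regions, and a command-line driver for dataset synthesis, training,
    prediction and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    generics,
    ggplot2,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
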