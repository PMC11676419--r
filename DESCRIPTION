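Package: strokeseg
Title: Dilated-Dense U-Net with Transformer Decoder Stages for Stroke Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Encoder-decoder semantic segmentation of ischemic stroke lesions in 2D
    brain-MRI slices. Implements dilated dense blocks (stacked atrous convolutions with
    rates 2/4/8 feeding a densely connected convolution block), compressing transition
    layers, and multi-head self-attention transformer blocks after each decoder
    upsampling stage, together with He-normal truncated initialization, four training
    losses (binary cross-entropy, soft Dice, sigmoid BCE and combined BCE-Dice), Dice
    and accuracy evaluation metrics, a NIfTI slice preprocessing and augmentation
    pipeline, an ablation-variant model factory, and a seeded synthetic lesion-phantom
    generator so the whole pipeline is testable without clinical data. Forward and
    backward passes are implemented natively with GEMM-based convolutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
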