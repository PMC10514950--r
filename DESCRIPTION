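Package: cytoseg
Title: Deep Ensemble Segmentation of Cervical Cytology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated cervical cell segmentation by deep ensemble
    learning. Cytoplasm and nucleus segmentation are treated as two independent
    binary semantic-segmentation tasks, each solved by a zoo of encoder-decoder
    convolutional networks (U-Net and U-Net++ decoders over ResNet and DenseNet
    encoders, plus DeepLabV3-family heads) whose probability maps are combined
    by unweighted averaging and thresholded at 0.5. Includes a seeded generator
    of Pap-stain-like synthetic images with exact ground truth, converters for
    MATLAB v7.3 (HDF5) containers, the full training recipe (real-time
    augmentation, class-weighted smoothed binary cross-entropy, Adam with
    lookahead, staged learning-rate decay, repeat-run selection by validation
    loss), and micro-averaged Dice/sensitivity/specificity evaluation with
    pixel-level bootstrap confidence intervals and paired bootstrap tests.
    Networks run on a compact built-in CPU engine (Rcpp/RcppArmadillo).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
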