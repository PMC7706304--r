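Package: spikeseg
Title: Fully Convolutional Segmentation of Wheat Spikes in Field Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of wheat spike (ear) regions in RGB field
    plot images with an FCN-8 encoder-decoder: a VGG16-style convolutional
    encoder, fully convolutional head, and a skip-connection decoder that
    fuses pool3/pool4 score maps with learned upsampling. Includes the full
    training recipe (pixelwise cross-entropy, momentum SGD with inverse-time
    learning-rate decay, He initialisation, dropout, early stopping on
    validation cost, a pretrained-encoder loading hook), random subimage
    sampling and sliding-window tiled inference, segmentation evaluation
    (global/class accuracy, IoU, precision-recall curves, per-growth-stage
    reports), and a synthetic wheat-plot scene generator with exact
    ground-truth masks so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    jpeg,
    tiff,
    yaml,
    jsonlite,
    optparse,
    stats,
    grDevices,
    graphics,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
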