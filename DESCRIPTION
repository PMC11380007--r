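Package: dpoa
Title: Dynamic Pelican Optimization with Image Preprocessing and
    Imbalance-Aware Loss Utilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Implements the pelican optimization algorithm (POA) and its
    dynamic variant (DPOA) with an exponentially decaying exploration
    intensity, together with a registry of classic benchmark functions and
    a multi-run statistics harness; non-local means denoising and
    contrast-limited adaptive histogram equalization for 8-bit raster
    images; stochastic affine augmentation; class-imbalance-aware loss
    functions (weighted cross-entropy, focal loss, dynamic per-iteration
    class weights derived from per-class error ratios); confusion-matrix
    classification metrics including the Matthews correlation coefficient;
    and synthetic generators for tissue-like test images and imbalanced
    four-class feature tasks. A derivative-free tuning demo couples the
    optimizer to a linear softmax classifier under the dynamic-weight loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
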