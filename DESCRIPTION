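Package: noduleCT
Title: Lung-Nodule CT Classification with Attention Residual U-Net
    Segmentation and a Hybrid Feature Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for binary lung-nodule classification on 2-D
    CT slices. Provides a synthetic CT-phantom generator with ground-truth
    masks, adaptive Gaussian denoising with PSNR/SSIM quality metrics, an
    attention residual U-Net segmenter (residual dual-channel attention
    blocks, PReLU and a tanh-gated sigmoid-weighted activation), a
    201-dimensional hybrid feature extractor (local Gabor transitional
    patterns, pyramid histograms of oriented gradients, PCA-compressed deep
    convolutional features and an entropy-weighted texture scalar), and a
    soft-voting ensemble of a transfer-learning LeNet-style classifier and a
    maxout network, together with full evaluation metrics (confusion-matrix
    statistics, ROC-AUC, repeat-run summaries) and stratified data splitting.
    All networks run on a small built-in CPU layer engine so the whole
    pipeline is reproducible at desk scale without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    yaml,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
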