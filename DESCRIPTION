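Package: ynetus
Title: Joint Segmentation and Classification of Lymph-Node Ultrasound with Y-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a Y-Net convolutional neural network for B-mode
    ultrasound images of cervical lymph nodes: a residual encoder with
    efficient-spatial-pyramid (ESP) dilated-convolution blocks and a
    pyramid-pooling bottleneck feeding two parallel heads, one producing a
    per-pixel lesion segmentation and one a benign/malignant classification.
    Includes image preprocessing (overlay stripping, canonical 256x256
    rescaling, augmentation), a joint cross-entropy training loop with
    patient-grouped splits and k-fold cross-validation, a complete
    diagnostic-metrics suite (Dice, sensitivity, specificity, accuracy,
    predictive values, likelihood ratios, ROC/AUC with Youden cutoff
    selection), a keyword dictionary classifier for free-text ultrasound
    report conclusions, and a seeded speckle-phantom generator that
    produces lymph-node-like synthetic datasets for end-to-end testing.
    All network layers run on the CPU via 'RcppArmadillo' with exact
    reverse-mode gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
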