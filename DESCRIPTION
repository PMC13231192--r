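Package: attnmil
Title: Dual-Attention Multiple-Instance Learning for Patient-Level
    Ultrasound Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised classification of patients from variable-sized
    bags of grayscale ultrasound-style images. Implements a dual-attention
    multiple-instance learning model: a per-instance spatial self-attention
    module with residual refinement of convolutional feature maps, followed by
    gated instance attention that aggregates a patient's images into a single
    bag embedding for benign/malignant prediction. Includes mean-pooling and
    max-pooling baselines sharing the same backbone, an SGD training loop with
    cosine warm-up and milestone decay, patient-level stratified train/test and
    k-fold cross-validation splitting, AUROC/AUPRC and operating-point metrics,
    attention-based instance ranking with top/tail galleries, and a synthetic
    speckle-textured bag generator with instance-level ground truth so the full
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
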