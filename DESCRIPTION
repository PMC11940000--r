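Package: emgrasp
Title: Cylindrical-Grasp Prediction from Surface EMG and Task Context
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting cylindrical grasps during
    reach-to-grasp movements from multichannel surface electromyography (sEMG)
    and task/product context. Provides sEMG envelope extraction (band-pass,
    rectification, low-pass, Gaussian smoothing) with per-subject maximum
    voluntary contraction (MVC) normalization; dataset curation (null trimming,
    reaching selection, length standardization, subject-wise partitioning);
    declarative specifications of three small neural architectures (an EMG 1-D
    convolutional branch, a fully connected context branch, and their late
    fusion) with exact trainable-parameter accounting; a self-contained
    training engine (Adam, cosine-decayed learning rate, best-validation
    checkpointing); and drivers for the unimodal-versus-multimodal comparison
    and the context-variable ablation study. A seeded synthetic-data generator
    emulates the structure of a 30-subject activities-of-daily-living sEMG
    dataset so the whole pipeline is testable without the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    arrow,
    jsonlite,
    ggplot2,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
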