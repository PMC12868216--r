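Package: osteoseg
Title: Leak-Free Deep-Learning Segmentation of Bone and Medullary Pores
    in Micro-CT Volumes
Version: 1.0.0
Authors@R:
    person("Osteoseg", "Developers", email = "osteoseg@example.org",
           role = c("aut", "cre"))
Description: A CPU-friendly toolkit for training and deploying 2D semantic
    segmentation models on volumetric micro-CT scans of long bones, with
    three classes (background, cortical bone, medullary pores). Provides
    scan-level (leak-free) train/validation splitting and k-fold
    cross-validation, per-scan normalization, probability-calibrated
    geometric and intensity augmentation, a compact U-Net trained with a
    soft Jaccard loss under single-cycle cosine annealing and Adam,
    overlap-aware chunked sliding-window inference with confidence-based
    background reassignment, class-wise and mean Intersection-over-Union
    evaluation with Dice conversion, a normalized performance-efficiency
    weighted model-ranking framework, and a synthetic long-bone phantom
    generator so every stage is testable without real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
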