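Package: phenopaint
Title: Trait-Conditioned Adversarial Synthesis of Crop Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for trait-to-image crop visualization. Extracts a panel of
    18 phenotypic traits (intensity texture statistics, silhouette morphology,
    box-counting fractal dimension, green/yellow colour areas) from segmented
    plant images, builds centred and resized training datasets with min-max
    trait normalization, trains a trait-conditioned multi-stage generative
    adversarial network that synthesizes plant images from trait vectors, and
    evaluates visual fidelity (structural similarity, Frechet distance between
    feature-space Gaussians) and trait-prediction accuracy (per-trait Pearson
    correlation, per-sample cosine similarity). Includes a seeded procedural
    generator of plant-like silhouettes so that the full pipeline can be
    trained and tested at desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    EBImage,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
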