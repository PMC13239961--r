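Package: rotqa
Title: Rotational Setup-Error Dose QA with Structural Similarity and Dosiomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies how rotational setup errors perturb stereotactic
    body radiotherapy (SBRT) dose distributions. Simulates multi-lobe
    high-gradient dose fields, applies rigid rotations about the isocenter,
    samples planar detector measurements, and scores structural degradation
    with the structural similarity index (SSIM) alongside gamma-index and
    dose-difference passing rates and the DVH-based delta-V100 metric.
    Extracts IBSI-style radiomic (first-order + 3D shape) and dosiomic
    (first-order + texture + wavelet) feature sets and predicts SSIM from
    them with gradient-boosted attribution-based feature selection, grouped
    train/test splitting and a fixed cross-validated model search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xgboost,
    glmnet,
    ranger
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
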