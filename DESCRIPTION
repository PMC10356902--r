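Package: explainleak
Title: Privacy Auditing of Explainable Image Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the membership-inference risk incurred by exposing
    model explanations alongside predictions. Generates a two-class synthetic
    concept benchmark (geometric shapes drawn on a lesion-like base blob, with
    per-concept presence labels and ground-truth masks), trains small
    convolutional victim classifiers under baseline, overfitting and
    differentially private (DP-SGD) regimes, computes attribution maps
    (saliency, occlusion), concept activation vectors (CAVs), TCAV scores and
    concept localization maps, and runs metric- and classifier-based
    membership inference attacks under optimal and suboptimal deployment
    scenarios. Reports attack AUC/accuracy grids and CAV quality statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    glmnet,
    e1071,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
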