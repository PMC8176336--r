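Package: hepadose
Title: Heparin Treatment Outcome Prediction and Dosage Recommendation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the response to unfractionated heparin in
    intensive care: a seeded synthetic cohort generator with a known monotone
    dose to activated partial thromboplastin time (aPTT) mechanism, a cohort
    construction chain (inclusion criteria, mean +/- 3 SD outlier filtering,
    3-nearest-neighbour imputation, one-hot encoding, min-max normalization),
    ternary therapeutic-outcome labelling, a fully connected shallow neural
    network classifier trained by full-batch gradient descent, confusion-matrix
    metrics (accuracy, Cohen's kappa, macro-averaged precision/recall/F1),
    leave-one-feature-out ablation importance, and a counterfactual dosage
    recommendation engine that sweeps candidate doses to maximize the predicted
    normal-therapeutic probability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
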