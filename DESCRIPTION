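Package: arcgate
Title: Gamma Passing Rate Class Prediction for VMAT Arcs from
    Control-Point Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the patient-specific quality assurance outcome of
    single-isocenter multi-target brain SRS/SRT VMAT arcs before
    measurement.  Each arc's control-point sequence (meterset weight,
    jaw positions, gantry angle, 120 MLC leaf positions) is encoded as a
    fixed-width numeric sequence, the continuous gamma passing rate is
    discretized into Ideal / Investigate / Replan classes, minority
    classes are balanced with SMOTE, and a stacked LSTM sequence
    classifier is trained with stratified many-fold cross-validation and
    early stopping.  Includes one-vs-all diagnostics (sensitivity,
    specificity, ROC/AUROC), a deliverability-constrained synthetic arc
    generator for end-to-end testing without clinical data, and a
    portable JSON model export with prediction-parity checking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    graphics,
    stats,
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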