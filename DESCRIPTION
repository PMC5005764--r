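Package: sbpred
Title: Ensemble Support Vector Machine Prediction of Streptavidin-Binding Peptides
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains, evaluates and applies an ensemble of radial-basis-function
    support vector machines that classifies short phage-display peptides as
    streptavidin binders or non-binders. Peptides are encoded as amino acid
    composition (20 features) or dipeptide composition (400 features);
    accuracy-ranked forward selection reduces either encoding to an optimized
    subset. Class imbalance between the few known streptavidin binders and the
    many non-binders is handled by repeated downsampling of the negative set,
    one submodel per balanced pair, with averaged calibrated probabilities and
    vote counts as the ensemble output. Includes stratified cross-validation,
    ROC/AUC, label-permutation significance testing, chi-square comparison of
    positive rates on independent sets, and a seeded synthetic benchmark
    generator for motif-carrying peptides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
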