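Package: meth4c
Title: Sequence-Based Prediction of DNA N4-Methylcytosine Sites
Version: 0.1.0
Authors@R:
    person("meth4c", "developers", email = "meth4c@example.org", role = c("aut", "cre"))
Description: Predicts DNA N4-methylcytosine (4mC) sites from 41-nt
    cytosine-centred sequence windows. Windows are encoded into a
    292-dimensional feature space built from five encoder families
    (one-hot binary, sequential nucleotide frequency, k-nucleotide
    frequency, k-spaced nucleotide pair frequency and pseudo dinucleotide
    composition). Feature dimensions are ranked by split-count importance
    from a gradient-boosted tree ensemble and pruned by backward
    elimination under cross-validated SVM performance; the final
    classifier is an RBF-kernel support vector machine with grid-searched
    hyperparameters and calibrated probability output. Includes a
    synthetic benchmark generator, evaluation utilities (Sn/Sp/ACC/MCC,
    ROC/AUC, stratified k-fold cross-validation, independent test) and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
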