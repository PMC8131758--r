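Package: mnscore
Title: Deep-Learning-Assisted Scoring of the In Vitro Micronucleus Assay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automating the in vitro micronucleus (MN) assay from
    two-channel (brightfield + DNA stain) single-cell images such as those
    produced by imaging flow cytometry. Provides a synthetic image generator
    with known ground truth for mononucleated, binucleated and polynucleated
    cells with and without micronuclei and for irregular morphologies; a
    six-class convolutional neural network classifier with deterministic
    training; an assisted ground-truth labeling engine based on embedding,
    over-clustering and linear-model prediction with an unknown fallback;
    exact per-class precision/recall/F1 accounting with truth-count-weighted
    averages; and OECD Test Guideline 487 genotoxicity and cytotoxicity
    statistics (CBPI cytostasis, relative-count cytotoxicity) with one-sided
    Fisher exact dose-response testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    nnet,
    vegan,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
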