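Package: puplearn
Title: Positive-Unlabeled Learning for Protein Pupylation Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts pupylation sites (lysine attachment of the prokaryotic
    ubiquitin-like protein Pup) from protein sequence using positive-unlabeled
    learning. Lysine-centered peptide windows are encoded as compositions of
    k-spaced amino-acid pairs (CKSAAP), features are ranked by chi-square
    statistics, and a three-stage algorithm mines reliable negatives from the
    unlabeled lysine pool around a radial-basis support vector machine:
    distance-based initial selection, iterative expansion with support-vector
    set compression, and a final classifier. Includes a balanced-negative SVM
    baseline, a support-vector-only expansion variant, rank-based ROC/AUC and
    Matthews-correlation evaluation with stratified cross-validation,
    calibrated score thresholds, ranking of nonannotated lysines, a synthetic
    proteome generator with planted sequence motifs and partial annotation for
    end-to-end benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
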