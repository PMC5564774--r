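Package: qsartox
Title: QSAR Modelling of Aquatic Toxicity by mRMR-GA-SVR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for quantitative structure-activity relationship (QSAR)
    modelling of the aquatic toxicity log(IGC50^-1) of aromatic compounds to
    Tetrahymena pyriformis. Computes graph-topological molecular descriptors
    (Kier-Hall connectivity and shape indices, Wiener, Randic and Balaban
    indices, electrotopological states, atom and group counts) from MOL/SDF
    V2000 records or SMILES strings; performs two-stage descriptor selection
    by minimum-redundancy-maximum-relevance (mRMR) mutual-information ranking
    followed by a genetic-algorithm wrapper scored by cross-validated support
    vector regression; trains epsilon-insensitive support vector regression
    with linear, polynomial and radial-basis kernels via a sequential minimal
    optimization solver written in C++; provides a NIPALS partial least
    squares baseline, RMSE/R2/Q2 validation metrics with k-fold
    cross-validation and (C, epsilon) grid search, leave-one-descriptor-out
    ablation, one-at-a-time sensitivity analysis, and a synthetic descriptor
    table generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
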