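Package: metabotox
Title: Metabolomic Fingerprinting and Mechanism Classification of Drug-Induced Hepatotoxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for cell-based LC-MS metabolomics screens of
    drug-induced liver injury. Provides a synthetic feature-table generator
    emulating a HepG2 exposure study (four analytical blocks, pooled QC and
    blank injections, mechanism-specific metabolite signatures for oxidative
    stress, phospholipidosis and steatosis), preprocessing (blank-based
    background filtering, internal-standard and protein normalization, block
    fusion, replicate averaging, log/autoscaling), a from-scratch NIPALS
    PLS2-DA core with VIP scores, Hotelling T2 ellipses and stratified
    repeated cross-validation (R2Y, Q2, misclassification error, multiclass
    AUROC), univariate discriminant testing with the dual q-value/VIP
    criterion, VIP-ranked variable selection, response-permutation model
    validation, external-set projection with confidence grading, and
    hypergeometric over-representation analysis of metabolite sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
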