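Package: nmrfusion
Title: Targeted 1H NMR Metabolomics Simulation, PLS-DA Variable
    Selection and Multi-Block Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates three-group 1H NMR metabolomics cohorts (serum,
    urine and muscle tissue spectra plus clinical covariates) with known
    ground truth, preprocesses spectra (chemical-shift referencing,
    segment-wise integer alignment, probabilistic quotient
    normalization), quantifies metabolites by targeted window
    integration, computes group-wise percentage differences, relative
    standard deviations and Student t tests, and models group separation
    with NIPALS PLS-DA, iterative VIP-based variable selection with
    jackknife confidence intervals, 7-fold cross-validated ROC/AUC
    evaluation and multi-block (serum + urine + tissue + clinical) data
    fusion.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
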