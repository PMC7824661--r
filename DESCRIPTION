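Package: vinometrics
Title: Chemometric Classification and Regression Workflows for Wine 1H NMR Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for variety authentication and compositional prediction of wine
    from bucketed 1D 1H NMR spectra. Implements total-intensity normalization and
    fixed-width spectral bucketing with solvent-region exclusion, an iterative
    double cross-validation ensemble classifier built on gradient-boosted trees,
    single-response partial least squares (NIPALS) regression with an RMSECV-based
    component-selection rule and Hotelling T-squared score-space outlier exclusion,
    genetic-algorithm variable selection, weighted one-vs-rest multiclass AUC, and
    a response-permutation engine for model validation. A synthetic wine-spectrum
    generator with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
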