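Package: glycoDCDR
Title: Drop-Coating Deposition Raman Chemometrics for Glycated Albumin
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and chemometric analysis of drop-coating deposition
    Raman (DCDR) spectra of human serum albumin and glycated albumin.
    Provides a SummarizedExperiment-based container for spectral datasets,
    a pseudo-Voigt band-model simulator of the two-class calibration design
    and of annular-ring 2D maps, principal component analysis with
    ridge-penalized logistic discrimination and permutation controls,
    NIPALS partial least squares calibration with leave-one-sample-out
    cross-validation, analytical figures of merit (relative error of
    prediction, precision profiles, and two IUPAC 3-sigma limit-of-detection
    estimators), and radial/angular summaries of concentration maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: Software, Spectroscopy, Classification, Regression, Metabolomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
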