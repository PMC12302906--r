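Package: fieldfit
Title: Predicting Diel Rice Gene Expression from Meteorological Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models diel gene expression dynamics of field- and
    growth-chamber-grown rice as a function of meteorological time series.
    Each gene is described by the sum of age, circadian-clock and gated
    environmental-response sub-models with interactions; linear coefficients
    are selected by an adaptive group LASSO and the seven nonlinear gate and
    window parameters by grid search refined with Nelder-Mead. Per gene, the
    better environmental predictor (temperature or irradiance) is chosen by
    an information criterion, and training-set-composition experiments
    (growth chamber, field, mixed pools) quantify predictor identifiability
    and held-out prediction error. Includes diel summary statistics
    (smoothing-spline amplitudes, paired-t differential expression with
    Benjamini-Hochberg control, temperature-correlation screens),
    plate-level sample-swap detection with leave-one-plate-out sparse
    temperature regression, cultivar genotype concordance checks, and a
    synthetic-data generator emulating the 73-condition growth-chamber
    factorial design and correlated field meteorology.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    glmnet,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
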