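Package: gmfab
Title: Generalized Matrix Factorization for Exponential-Family Data Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimation of generalized matrix factorization (GMF) models for
    matrices of counts or continuous measurements arising in bulk and
    single-cell transcriptomics. The linear predictor combines row- and
    column-covariate regression effects with a low-rank latent factorization,
    linked to exponential-dispersion-family responses (Gaussian, Poisson,
    binomial, gamma, negative binomial, quasi-Poisson). Parameters are
    estimated by penalized quasi-likelihood using alternated iterative
    re-weighted least squares, a diagonal quasi-Newton method, or a block-wise
    adaptive stochastic gradient descent with minibatch subsampling. The
    package also provides structured null-residual initialization,
    model-based imputation of missing entries, identifiability projections,
    rank selection by information criteria, entrywise-holdout
    cross-validation and spectral rules, out-of-sample reconstruction
    metrics, and simulators for exact-model and single-cell-like count data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: DimensionReduction, SingleCell, RNASeq, Regression, Software
RoxygenNote: 7.3.3
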