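Package: gsemCortex
Title: Multivariate Genomic Architecture of Brain Structure via Genomic
    Structural Equation Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the joint genetic architecture of many GWAS traits
    from summary statistics and models it with latent genomic factors.
    Implements multivariable LD-score regression with a multivariate block
    jackknife to obtain a genetic covariance matrix and its sampling
    covariance, exploratory factor analysis of genetic correlations with
    non-graphical scree rules, confirmatory common/correlated/bifactor
    models fit by diagonally weighted least squares with sandwich standard
    errors and residual-covariance search, stratified (partitioned)
    enrichment of genomic-factor variances across functional annotations,
    spherical spin-permutation tests for comparing factor parcellations
    with cortical maps, and a fully seeded synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'sumstats.R'
    'ldsc.R'
    'factor-structure.R'
    'sem-model.R'
    'sem-fit.R'
    'stratified.R'
    'spin.R'
    'simulate.R'
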