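Package: circaluc
Title: Period Estimation and Temperature Compensation Analysis for
    Luciferase Reporter Rhythms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for circadian bioluminescence recordings of
    luciferase reporter constructs (counts-per-second time series from
    plate readers). Trims the light:dark entrainment segment, isolates the
    free run in constant darkness, detrends with a centred moving average,
    estimates the free-running period by damped-cosine least squares with
    a multi-start period grid, scores rhythm quality as one minus the
    Pearson correlation between fit and detrended data, filters fits by
    error cutoffs, aggregates per genotype/tissue/temperature group,
    computes Q10 temperature-compensation coefficients, and provides
    shared-control estimation statistics (bootstrap mean differences with
    BCa or percentile confidence intervals). Includes a synthetic cohort
    generator for damped circadian oscillators with Poisson or Gaussian
    counting noise and a temperature-to-period relation parameterised by a
    true Q10, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    boot,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort.R'
    'estimation.R'
    'fit.R'
    'io.R'
    'methods-LumiSeries.R'
    'pipeline.R'
    'preprocess.R'
    'simulate.R'
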