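Package: didconfound
Title: Confounding and Adjustment in Difference-in-Differences Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying confounding in
    difference-in-differences designs. Generates balanced panels under nine
    parameterized confounding scenarios (time-invariant and time-varying
    covariates, constant and time-varying covariate effects, and
    treatment-affected covariates), applies six estimators of the average
    treatment effect on the treated (simple, covariate-adjusted and
    time-varying-adjusted two-way regressions with cluster-robust standard
    errors, plus three nearest-neighbor matching strategies), and summarizes
    Monte Carlo bias, mean standard error, and root mean squared error.
    Closed-form diagnostics classify each data-generating process by whether
    it violates the parallel-trends assumption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    ggplot2,
    optparse
Config/testthat/edition: 3
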