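Package: cerradosim
Title: Spatially Explicit Simulation of Native Vegetation Loss Under
    Property-Level Legal Reserve Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates Bayesian logistic models of native-vegetation
    conversion from gridded driver variables over successive two-year
    periods (random-walk Metropolis MCMC, held-out-likelihood model
    selection, AUC validation), projects loss forward by Monte Carlo
    simulation of binary change maps under Legal Reserve and
    protected-area constraints on private rural properties, ensembles
    period-specific models, and quantifies policy scenarios (for
    example, protecting a fixed share of large properties) by
    property-size class. Includes a fully synthetic landscape generator
    (autocorrelated driver fields, distance transforms, a heavy-tailed
    property mosaic, conversion histories from known coefficients) so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
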