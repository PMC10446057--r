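Package: twozone
Title: Probabilistic Two-Zone Near-Field/Far-Field Occupational Exposure
    Modelling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Exact solution of the two-compartment (Near-Field/Far-Field)
    mass-balance model for indoor contaminant dispersion, with Monte-Carlo
    simulation of multi-task work shifts under sampled operational
    conditions. Computes exposure summary statistics (geometric mean and
    geometric standard deviation, percentiles, 8-h time-weighted averages
    per substance), job and task sensitivity analyses (Spearman-based),
    estimation of the inter-zonal airflow and emission rates from
    stationary concentration traces, and EN 689 / risk-characterization
    compliance verdicts against occupational exposure limit values.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
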