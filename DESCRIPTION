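Package: cnddtools
Title: Estimating Stabilizing Conspecific Negative Density Dependence in Tree Mortality
Version: 0.1.0
Authors@R:
    person("Forest", "Dynamics Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for estimating stabilizing conspecific negative
    density dependence (CNDD) from repeated forest-census data. Computes
    kernel-weighted conspecific and total neighborhood densities, fits
    species-site-specific discrete-time survival models (binomial GAMs with a
    complementary log-log link and census-interval offset), converts fits into
    comparable average marginal effects on the mortality-probability scale with
    simulation-based uncertainty, and aggregates species-site estimates with
    multilevel measurement-error meta-regressions to test latitudinal and
    abundance-related patterns. Includes a synthetic multi-site forest
    generator with known ground-truth CNDD, robustness machinery
    (randomizations, influence filtering, spatial-autocorrelation screening,
    life-history confounder models), and a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    mgcv,
    MASS,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
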