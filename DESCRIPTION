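Package: trapcal
Title: Bayesian Calibration of Mosquito Trap Catches Against Human Landing Catch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating exposure-free mosquito traps against the
    human landing catch (HLC). Nightly trap counts are related to HLC counts
    through four nested mean models (linear, intraspecific density
    dependence, pooled and per-taxon interspecific density dependence) under
    a negative binomial likelihood formulated as a Gamma-Poisson mixture,
    fitted by an adaptive Metropolis-within-Gibbs sampler with gamma priors
    that constrain the trap-to-HLC relationship to be positive and pass
    through the origin. Includes model comparison by deviance information
    criterion (DIC), pseudo-R-squared and held-out root-mean-square error,
    HLC-equivalent prediction with credible intervals, lookup-table
    generation, a validated overdispersed synthetic-data generator, and
    utilities for fitting zero-intercept power-law curves to published
    conversion tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
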