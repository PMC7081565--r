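Package: arealbhm
Title: Geographic Identifier Imputation and Spatio-Temporal Bayesian
    Hierarchical Modeling for Misaligned Small-Area Health Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for small-area analyses of health-service utilization
    records whose fine-scale geographic identifiers (e.g., census tracts)
    are partially missing while a coarser, spatially misaligned identifier
    (e.g., ZIP code) is known.  Provides a stochastic areal-proportion
    algorithm that assigns missing tract identifiers from a tract-in-ZIP
    crosswalk, replicate assignment datasets and complete-case contrasts,
    aggregation to tract-year count panels with expected counts, a
    spatio-temporal Bayesian hierarchical Poisson model with intrinsic CAR
    and exchangeable random effects at two spatial scales plus a temporal
    trend, Gibbs variable selection with Bernoulli entry parameters over
    correlated neighborhood covariates, conditional predictive ordinate
    (CPO) and log pseudo marginal likelihood (LPML) model comparison, and
    a synthetic-data generator producing misaligned areal geographies with
    rural-biased geographic missingness for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
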