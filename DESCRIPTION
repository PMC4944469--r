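Package: lactscale
Title: Allometric Scaling of Maternal Energy Intake During Lactation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how the elevation of maternal metabolizable
    energy intake (MEI) during lactation scales with body mass across mammals.
    Extracts the raw characteristics of an intake-elevation pattern (initial,
    peak and average rate, amplitude, time to peak, cumulative elevation to
    peak), decomposes cumulative intake elevation with a generalized Von
    Bertalanffy growth curve and derives a dimensionless shape statistic, and
    fits curvilinear log-log scaling regressions with a mass-dependent
    exponent, a diet energy-density covariate and species/breed random
    effects, both by REML and by a phylogenetic animal-model Gibbs sampler
    that reports the phylogenetic signal lambda. Includes a synthetic-data
    generator with phylogenetically structured species effects so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    lme4,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
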