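Package: heatfec
Title: Reproductive Performance of a Predator-Prey Mite Couple Under
    Simulated Heat Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for repeated-measures reproduction experiments
    in which individually caged arthropod females (a predatory mite and its
    spider-mite prey) are observed daily under programmed mild or extreme
    diurnal heat-wave regimes.  Provides the bi-hourly incubator regime
    profiles, an individual-based synthetic-cohort generator with competing
    daily escape and death hazards, Kaplan-Meier escape and survival
    functions with the Gehan-Breslow (generalized Wilcoxon) homogeneity
    test, nonlinear and cluster-robust log-linear fitting of a gamma-shaped
    age-dependent rate model for oviposition, predation and egg volume,
    delta-method ratio-of-means comparisons of heat-wave effects,
    overdispersion-scaled factorial generalized linear models for feeding,
    fecundity and offspring sex ratios, egg morphometrics, and a
    reproducible end-to-end pipeline over flat CSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    sandwich,
    survival,
    MASS,
    yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
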