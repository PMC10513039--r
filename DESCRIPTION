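Package: wkppg
Title: Windkessel Simulation and Temporal-Complexity Analysis of Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates peripheral blood pressure and photoplethysmography (PPG)
    with a modified four-element Windkessel model whose central compliance
    varies with central pressure within each cardiac cycle (Langewouters
    arctangent pressure-area law).  Provides pulse and continuous stimulus
    protocols, PPG morphological features, Higuchi fractal-dimension and
    autocorrelation half-width complexity measures, per-subject hemodynamic
    fitting, and a feature-to-blood-pressure evaluation harness
    (leave-one-subject-out linear and Bayesian-regularized neural-network
    models with ensemble undersampling).  A synthetic multi-channel cohort
    generator with known ground-truth hemodynamics makes every stage testable
    without access to experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
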