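Package: westvq
Title: Multicompartment V/Q Lung Model Simulation and Deep-Learning
    Recovery of West Model Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates steady-state pulmonary gas exchange with a
    multicompartment (West-type) ventilation/perfusion lung model, including
    arterial nitrogen pressure (PaN2), full oxygen/carbon-dioxide/nitrogen
    blood chemistry and acid-base balance. Generates randomized cohorts of
    simulated monitoring data, trains feed-forward neural networks to recover
    the three defining distribution parameters (shunt, logSD, mean V/Q) from
    ten single-measurement monitoring inputs, and provides the evaluation
    machinery: predicted-versus-true regression, Scott-rule kernel density
    estimates, exact Shapley-value sensitivity analysis, and dilution-based
    estimation of "true" (Zone 1) alveolar dead space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    MASS
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    arrow,
    optparse,
    withr
Config/testthat/edition: 3
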