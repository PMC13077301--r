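Package: phagedyn
Title: Phage-Bacteria Community Dynamics with Density-Dependent Infection Attenuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compartmental SEIV and SEIVD (debris-attenuated) models of lytic
    phage-bacteria population dynamics at pairwise and multi-strain community
    scale, with Erlang-distributed latent periods via the linear chain trick.
    Includes conventional life-history trait estimators from growth,
    adsorption, and one-step growth assays; Bayesian trait inference by
    delayed-rejection adaptive Metropolis (DRAM) with truncated-normal and
    log-normal priors, convergence and posterior-predictive diagnostics, and a
    Bayesian test of practical equivalence for comparing pairwise versus
    community-inferred traits; and synthetic-data generators that emulate
    one-step growth curves, multi-cycle pairwise infections, and a
    five-host/five-phage community experiment for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
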