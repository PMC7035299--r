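Package: spatphage
Title: Stochastic Spatial Models of Phage-Bacteria Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the transient dynamics of virulent bacteriophages
    attacking bacteria in structured environments, across four nested levels
    of detail: well-mixed Lotka-Volterra dynamics with Monod nutrient
    depletion, an Erlang-distributed (10-stage) latent period, a stochastic
    3-D reaction-diffusion lattice with tau-leaping event sampling, and
    colony-level protection (Smoluchowski 1/3-exponent adsorption to
    microcolonies, exponential shielding by infected surface cells, and
    readsorption of progeny phages). Includes harnesses for trajectory
    studies, survival phase diagrams over initial densities, and replication
    of soft-agar plating experiments, with tidy tabular outputs and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
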