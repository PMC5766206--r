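Package: ribochain
Title: Model-Based Design and Analysis of RNA Hybridization Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermodynamic modelling and sequence design for networks of
    interacting regulatory RNAs (toehold-mediated riboregulator cascades).
    Provides a pluggable secondary-structure energy engine (an internal
    stacking-only nearest-neighbour model plus a ViennaRNA command-line
    adapter), per-interaction hybridization and activation free energies,
    toehold detection, hierarchical complex assembly, cross-talk matrices,
    an empirical linear design objective, Monte Carlo simulated-annealing
    sequence optimization, mass-action equilibrium with apparent
    dissociation constants derived from gel band mass fractions, and the
    correlation analyses used to confront predicted energies with measured
    activities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
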