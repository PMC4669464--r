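Package: vcmme
Title: Variance-Corrected Michaelis-Menten Kinetics for Fluctuating
    Substrate and Transcription-Factor Concentrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for enzyme and gene-regulation kinetics under stochastic
    substrate fluctuations. Implements the Michaelis-Menten rate law together
    with exact Jensen (upper) and Taylor-remainder (lower) bounds on the
    ensemble-averaged rate, the variance-corrected Michaelis-Menten equation
    (VCMME) and its higher-order Taylor refinements; exact-event Gillespie
    simulators for bursty-substrate enzymatic reactions and for a
    transcription-factor expression cascade with translational bursting,
    multi-step maturation delays, dilution and operator binding; and the exact
    analytical model of the transcription-factor concentration (hypoexponential
    delay density, Laplace functional of the delayed shot-noise process, mean
    and variance time courses, operator-occupancy integrals and their MME,
    VCMME and Poisson approximations). Includes named fixture parameter sets,
    an experiment driver with TSV output and sidecar metadata, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
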