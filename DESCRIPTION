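Package: sigmux
Title: Multiplexing Capacity of Stochastic Signalling Systems
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how well a noisy dynamic signalling system can
    multiplex several input signals. Implements the phase-corrected linear
    noise approximation (pcLNA) for stochastic oscillatory reaction networks,
    Fisher-information and sensitivity-matrix computation in log-parameter
    space, a QR-based multiplexing-capacity calculus, Blahut-Arimoto channel
    capacity estimation for scalar dose channels, exact Gillespie simulation,
    and built-in NF-kB pathway model variants with post-translational
    modification states.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
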