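Package: dynswitch
Title: Dynamic Bistable Switches in Cell-Cycle Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of bistable biochemical switches whose
    response curve changes dynamically in time. Implements deterministic,
    delayed, Langevin, discrete-stochastic (Gillespie) and one-dimensional
    reaction-diffusion versions of a two-feedback protein activation switch,
    a two-compartment (nucleus/cytoplasm) model of mitotic entry, a
    pseudo-arclength continuation routine for steady-state response curves
    and saddle-node detection, threshold-based period/amplitude and
    transition-time detectors, and robustness statistics (coefficients of
    variation, oscillatory-region maps, random parameter surveys).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
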