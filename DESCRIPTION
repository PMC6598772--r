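Package: hexgait
Title: Quantitative Analysis of Hexapod Limb Coordination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing limb coordination in walking hexapods from
    per-frame limb and body kinematics: swing/stance classification and
    per-step parameters, instantaneous limb phase via the discrete-time
    analytic signal, circular statistics of relative phases, Kuramoto-style
    coherence against canonical gait templates (tripod, tetrapod, wave),
    nonlinear manifold embedding of limb-trajectory segments, turning
    asymmetry analyses, and perturbation-triggered slowing analyses.
    Includes two generative models - a one-parameter six-limb phase
    oscillator producing metachronal waves and a coupled-Hopf canonical
    gait simulator - that serve as a fully parameterised synthetic-data
    source for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    withr,
    ggplot2,
    generics,
    stats,
    signal,
    minpack.lm,
    deSolve,
    uwot,
    RANN,
    igraph,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    jsonlite,
    knitr
Config/testthat/edition: 3
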