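Package: eicrit
Title: Self-Organized Criticality in Excitatory-Inhibitory Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of excitatory-inhibitory (E-I) spiking
    neuronal populations that self-organize toward a Bogdanov-Takens (BT)
    critical point through spike-timing-dependent plasticity (STDP) and
    Tsodyks-Markram short-term synaptic depression (STP). Provides a
    conductance-based leaky integrate-and-fire network simulator with a
    compiled core, online STDP on all four synapse classes and STP on
    excitatory-to-excitatory synapses, a two-population rate (mean-field)
    model with fixed-point, nullcline and BT-residual analysis, an exact
    two-state Markov population model with linear-noise (system-size
    expansion) variance formulas, a directed-percolation Langevin field
    layer with an STP-coupled efficacy field, and an avalanche-statistics
    toolkit (detection, power-law fitting, branching-ratio estimation,
    inter-spike-interval variability, shape collapse, size-duration
    scaling) together with ground-truth synthetic generators for testing
    every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    pracma,
    stats,
    yaml,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
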