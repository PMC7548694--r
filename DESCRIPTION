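Package: swrnet
Title: Disinhibition-Based Spiking and Rate Models of Hippocampal Sharp Wave-Ripples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of sharp wave-ripple (SWR) generation in a
    CA3-like network of pyramidal cells, parvalbumin-positive basket cells and
    anti-SWR interneurons. Provides a clock-driven conductance-based
    leaky integrate-and-fire simulator with short-term synaptic depression and
    facilitation, an LFP proxy and SWR event-quantification pipeline, a
    principled reduction to a three-population rate model (state-dependent f-I
    curve measurement, softplus fitting, membrane-potential optimization,
    shot-noise input generation), and a fixed-point/continuation engine that
    characterizes the bistability underlying SWR initiation and termination.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
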