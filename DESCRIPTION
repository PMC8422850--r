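Package: kneuron
Title: Conductance-Based Models of AVPV Kisspeptin Neurons Across the Estrous Cycle
Version: 0.1.0
Authors@R:
    person("kneuron", "developers", email = "kneuron@example.org", role = c("aut", "cre"))
Description: Single-compartment Hodgkin-Huxley style models of anteroventral
    periventricular (AVPV) kisspeptin neurons in diestrus and proestrus, with
    seven voltage-gated conductances (three GHK-driven K+ currents, persistent
    Na+, T-type Ca2+, HCN, and a three-state Markov transient Na+ channel) plus
    leak. Includes simulated voltage-clamp and current-clamp step protocols,
    the whole-cell analysis chain (leak and P/N subtraction, GHK permeability
    conversion, Boltzmann and exponential fitting), spike and F-I analysis,
    particle-swarm optimization of maximal conductances, conductance-swap
    experiments, and a synthetic whole-cell recording generator for end-to-end
    pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
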