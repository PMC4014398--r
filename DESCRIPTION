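Package: stochaxon
Title: Stochastic Simulation of Action Potential Waveform Variability in Thin Axons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discrete Markov ion-channel gating (binomial algorithm) on a
    compartmental cable model of unmyelinated axons. Simulates travelling
    action potentials whose waveform variability arises solely from channel
    noise, quantifies width and height statistics and their inverse power-law
    scaling with axon diameter, and propagates the arriving waveforms through
    a deterministic presynaptic Ca++ channel, a local Ca++ transient and an
    allosteric five-site vesicle-release model to predict the variability of
    synaptic responses.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
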