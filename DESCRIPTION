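Package: tacsnet
Title: Spiking-Network Simulation of tACS-Driven Synaptic Plasticity in
    Heterogeneous Cortical Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates leaky integrate-and-fire (LIF) networks with
    heterogeneous membrane time constants under sinusoidal, tACS-like
    stimulation, with soft-bound symmetric Hebbian spike-timing-dependent
    plasticity. Provides builders for a two-neuron pair motif, a balanced
    excitatory/inhibitory cortical layer, and a four-layer laminar network;
    epoched pre/stimulation/post protocols; frequency-by-timescale sweeps;
    and the analysis pipeline (firing rates, stimulation-phase histograms
    and vector strength, spike-timing-difference distributions, timescale-
    grouped weight trajectories, and net weight-change matrices), together
    with analytic oracles for the membrane dynamics and an integral
    predictor of mean synaptic weight change.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
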