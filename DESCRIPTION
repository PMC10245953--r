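Package: cbnsim
Title: Simulation of Cerebellar Nuclei Neuron Firing Under Convergent
    Purkinje-Cell Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how variably-sized inhibitory Purkinje-cell
    synapses control the firing rate and spike timing of cerebellar nuclei
    neurons. Generates synthetic Purkinje-cell spike trains with realistic
    lognormal interspike-interval statistics, synthesizes excitatory and
    inhibitory synaptic conductance waveforms by biexponential kernel
    convolution, integrates a point-conductance leaky integrate-and-fire
    neuron, and provides the spike-train statistics used to characterize
    the input-output transformation: firing rates, interspike-interval
    moments, auto- and cross-correlograms, spike-triggered average
    conductances, and the excitation/inhibition/half-decay metrics of
    normalized cross-correlograms. Scenario runners wire the stages into
    rate-code, conductance-variability, input-size and synchrony
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
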