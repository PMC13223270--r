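Package: silencenet
Title: Neuronal Silence Biomarkers, Seizure Prediction and Closed-Loop
    Suppression in Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for intermittent seizure-like
    synchronization in conductance-based spiking neuronal networks. Integrates
    Hodgkin-Huxley dynamics with a slow potassium (M-type) adaptation current
    and conductance-jump synapses on directed excitatory/inhibitory networks;
    computes spike-train synchrony and burst metrics (Kuramoto order parameter
    from interpolated spike phases, global and instantaneous interspike-interval
    coefficient of variation, per-neuron and network mean silence time);
    segments up (burst-synchronized) and down (asynchronous) states; predicts
    up-state onsets from the mean-silence-time biomarker by threshold crossing
    and by random-forest regression on lagged features; and runs a closed-loop
    stimulation controller that delivers a depolarizing current to a targeted
    neuron subset when prolonged network silence is detected, shortening
    seizure-like events. Includes readers for sorted multiunit spike tables and
    seeded surrogate generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
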