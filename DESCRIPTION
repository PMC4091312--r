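Package: neurofitr
Title: Fitting Neuronal Model Parameters to Electrophysiological Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modular framework for fitting the parameters of neuronal models to
    voltage- or current-clamp recordings. Simulated traces are compared to target
    traces through a library of normalized cost functions (pointwise errors,
    spike-timing and spike-shape features, and phase-plane trajectory density),
    combined as a weighted sum and minimized with bound-constrained global and
    local optimizers (an evolutionary algorithm with weak elitism, simulated
    annealing, Nelder-Mead, and L-BFGS-B). Built-in simulation backends cover a
    single-compartment Hodgkin-Huxley model, a double-exponential conductance
    synapse under ideal voltage clamp, and the adaptive exponential
    integrate-and-fire model; arbitrary external simulators are supported
    through a file-based black-box contract. Fits are driven either
    programmatically or from an XML configuration file, and produce text,
    figure, and HTML report artifacts. Surrogate-data generators with known
    ground-truth parameters support parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
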