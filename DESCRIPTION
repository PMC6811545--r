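Package: barrelsim
Title: Thalamocortical Integration and Layer-4 Barrel Circuit Simulation in
    Fmr1-KO and Wild-Type Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying feed-forward
    inhibition (FFI) and recurrent network dysfunction in layer 4 of the
    developing barrel cortex in the Fmr1 knock-out mouse model of Fragile X
    syndrome.  Provides genotype-specific parameter sets for stellate cells
    and fast-spiking interneurons, a two-factor short-term synaptic
    depression model with multi-frequency Levenberg-Marquardt fitting,
    conductance-based leaky integrate-and-fire single-cell and recurrent
    network simulators (AMPA, NMDA with voltage-dependent magnesium block,
    and GABA-A synapses), spike-train metrics (Gaussian spike density
    functions, van Rossum distance, first-spike latency and jitter),
    regularised linear population decoding of oddball stimuli with
    leave-one-out cross-validation, and membrane impedance (ZAP) analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
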