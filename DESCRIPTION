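Package: neuroperc
Title: Neuropercolation and Metabolically Coupled Spiking-Network Simulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and analysis tools for two models of metastable
    cortical dynamics. The first is a neuropercolation activation process on a
    torus lattice augmented with distance-dependent random long-range edges,
    together with its annealed mean-field map, critical initial-activation
    density, phase diagrams over the expected long-edge degree, and
    finite-size Monte Carlo estimates of the critical density. The second is a
    capillary-astrocyte-neuron (CAN) model coupling Izhikevich spiking units
    to astrocyte glycogen and mitochondrial ATP pools, in which metabolic
    state feeds back on neuronal excitability. Analysis utilities compute
    Kuramoto-style synchrony order parameters from spike rasters, classify
    high/low-synchrony states with hysteretic thresholds, measure dwell
    times, run hysteresis and cusp-bifurcation parameter sweeps, and fit
    phase cones to lattice phase fields. Includes JSON-configured run
    orchestration with CSV outputs and deterministic fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
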