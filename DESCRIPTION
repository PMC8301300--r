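Package: stdwaves
Title: EEG-Like Brain Waves from Excitatory-Inhibitory Networks with
    Short-Term Synaptic Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a balanced excitatory/inhibitory integrate-and-fire
    neural module on a 2-D periodic lattice whose synapses undergo
    short-term depression (Tsodyks-type resource dynamics), and analyses
    the emergent EEG-like population oscillations.  Provides the lattice
    and small-world connectivity generators, the depressing-synapse and
    membrane kernels, a fast compiled simulation engine with Poisson
    external drive and adiabatic parameter-sweep protocols, and the
    analysis layer: Welch power spectra, band powers, oscillation
    amplitude, firing rates, hysteresis/phase-transition detection,
    (noise, recovery-time) phase diagrams and slow/fast (delta-theta
    versus beta-gamma) rhythm-coexistence metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
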