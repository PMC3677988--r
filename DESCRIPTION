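Package: cannstd
Title: Continuous Attractor Networks with Short-Term Synaptic Depression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates rate-based continuous attractor neural networks
    (ring models) with short-term synaptic depression and divisive
    inhibition, driven by multi-component Gaussian stimuli with
    piecewise-constant amplitude fluctuations.  Provides the readout
    toolkit for temporally modulated population spikes: thresholded
    peak-position statistics, histograms and bimodality detection,
    resolution curves for overlapping stimuli, time-averaged tuning
    profiles, dynamical-regime classification and phase diagrams, and
    bias-conditioned spike-position maps.  Includes no-depression,
    local-inhibition and purely feedforward model variants, exact replay
    of stochastic input sequences, and plain-text serialization of runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
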