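Package: mmddm
Title: Multi-Mode Drift-Diffusion Modelling of Neural Population Activity
    During Evidence Accumulation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits a one-dimensional bounded evidence-accumulation state-space
    model with Poisson spike-train emissions in which the encoding weight of
    each neuron switches at decision commitment (the multi-mode drift-diffusion
    model, MMDDM). Provides a generative simulator of the pulsatile auditory
    click task including sensory adaptation, discretized forward-backward
    inference of the latent decision variable, joint maximum a posteriori
    parameter learning, single-trial inference of the neurally-inferred time of
    commitment (nTc), and the downstream analyses: peri-stimulus and
    peri-commitment time histograms, choice selectivity, engagement indices,
    state-space trajectories, psychometric curves and nTc-aligned
    psychophysical kernels with a lapse parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
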