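Package: retinacode
Title: Bayesian Image Reconstruction from Retinal Ganglion Cell Spike Trains
Version: 0.1.0
Authors@R:
    person("Retinacode", "Developers", email = "retinacode@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how populations of primate retinal ganglion
    cells (RGCs) encode natural images in the presence of fixational drift eye
    movements. Provides a synthetic stimulus generator (1/F textures, Brownian
    drift trajectories, flashed and jittered movies), a coupled Bernoulli
    generalized linear encoding model (LNBRC) of RGC spiking with simulator and
    FISTA-based fitter, exact 1/F and Gaussian image priors plus a trainable
    stand-in denoiser prior, plug-and-play MAP image reconstruction via
    half-quadratic variable splitting, joint image and eye-trajectory inference
    by particle-filter expectation-maximization, and evaluation utilities
    (masked multi-scale SSIM, PSTHs, shift-predictor-corrected
    cross-correlograms, spike-time perturbation, repeat shuffling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    jsonlite,
    splines,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
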