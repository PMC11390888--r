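# retinacode

Bayesian reconstruction of natural images from retinal ganglion cell (RGC)
spike trains, with fixational drift eye movements.

The retina encodes a visual scene in the spikes of mosaics of ON/OFF parasol
and midget ganglion cells while the eye incessantly drifts. `retinacode` is
a research toolbox for asking, on fully synthetic but physiologically
structured data, how much of the image those spikes carry: it simulates the
retina, fits the encoding model back from spikes, inverts it with natural
image priors, and measures what was recovered — including the case where the
drift trajectory is unknown and must be inferred jointly with the image.

## The models

**Encoding (LNBRC).** Cell *i* spikes in 1 ms bins as a Bernoulli process
with probability `sigmoid(g_i[t])`, where the generator signal

```
g_i[t] = m_i' v[t-1] + (s_i * f_i)[t-1] + sum_{j in N_i} (s_j * c_ij)[t-1] + b_i
```

sums a rank-1 spatiotemporal stimulus filter, a spike-history (feedback)
kernel, coupling kernels from neighbouring cells, and a bias — a coupled GLM
whose negative log-likelihood `sum_t [log(1 + exp(g)) - s g]` is convex.
Fitting alternates the two convex sides of the rank-1 factorization with
FISTA under an L1 penalty (spatial sparsity) and a group-L2,1 penalty
(coupling sparsity). An uncoupled variant (LNBR) and a Poisson benchmark
(LNP) are included.

**Decoding (plug-and-play MAP).** Images are reconstructed by maximizing
likelihood times prior, split into an encoding sub-problem (convex) and a
prior sub-problem solved by a proximal map or one denoiser call at noise sd
`sqrt(lambda/rho)`, alternated along an increasing `rho` schedule. Priors:
exact 1/F spectral Gaussian (`lambda * sum_k |a_k|^2 / f_k^2`), general
Fourier-diagonal Gaussians, and a trainable stand-in denoiser (learned
spectral Wiener filter). With unknown eye movements, a particle-filter EM
alternates image updates with sequential importance resampling over
Brownian drift trajectories, followed by backward smoothing and a final
reconstruction conditioned on the smoothed path.

**Evaluation.** Masked multi-scale SSIM (maximized over integer shifts —
the absolute position of a jointly estimated image is a gauge freedom),
PSTHs, shift-predictor-corrected cross-correlograms, spike-time
perturbation, repeat shuffling, and drift-magnitude / eye-position-error
metrics.

## Worked example

Simulate a drifting-image trial on a synthetic mosaic, then reconstruct the
image twice: assuming (incorrectly) that the eye never moved, and jointly
estimating the trajectory from the spikes alone.

```r
library(retinacode)

geom    <- encoder_geometry(32, 32, pixel_pitch_um = 11)
mosaic  <- build_mosaic(field_size_um = c(352, 352), seed = 1)
mosaic
#> <rgc_mosaic> 71 cells over 352 x 352 um (OFF_midget:25, OFF_parasol:5, ON_midget:33, ON_parasol:8)

encoder    <- sample_ground_truth_params(mosaic, geom, seed = 2)
image      <- generate_texture_image(seed = 3, 32, 32)      # 1/F texture
trajectory <- simulate_drift_trajectory(60, diffusion_um2_per_frame = 10, seed = 4)
realized_drift_magnitude(trajectory)
#> 24.5 um

stimulus <- drift_stimulus_set(list(image), list(trajectory))
spikes   <- simulate_spikes(encoder, stimulus, mode = "network", seed = 5)
spikes
#> <spike_trains> 71 cells x 500 ms, mean rate 28.8 Hz

mask     <- valid_region(mosaic, geom)
denoiser <- train_stand_in_denoiser(
  lapply(1:200, function(i) generate_texture_image(5000 + i, 32, 32)))

joint <- reconstruct_joint_em(spikes, encoder, denoiser,
                              trial_timing("drift", 60),
                              lambda = 0.1, mask = mask, seed = 6)
zero  <- reconstruct_known_em(spikes, encoder, denoiser, zero_trajectory(60),
                              lambda = 0.1, timing = trial_timing("drift", 60),
                              mask = mask)

ms_ssim_masked(joint$image, unclass(image), mask, max_shift_px = 5)$score  # 0.668
ms_ssim_masked(zero$image,  unclass(image), mask, max_shift_px = 2)$score  # 0.569
eye_position_error(trajectory, joint$trajectory)$mean                      # 12.2 um
eye_position_error(trajectory, matrix(0, 60, 2))$mean                      # 22.2 um
```

Reading the numbers: the image reconstructed *jointly with* the unknown eye
trajectory scores MS-SSIM 0.668 against the true texture inside the valid
region, versus 0.569 when the decoder wrongly assumes a stationary eye —
compensating for drift recovers image structure that the zero-movement
decoder blurs away. The inferred trajectory tracks the true eye position to
12.2 um on average (about one pixel), roughly half the error of assuming no
movement (22.2 um).

`run_experiment()` chains the whole pipeline (simulate → optionally fit →
reconstruct → evaluate) from a single seeded JSON-serializable config and
writes tidy metrics; `exec/retinacode` exposes `run`, `validate`, and
`simulate-stimulus` subcommands.

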