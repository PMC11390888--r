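---
title: "Models and methods for Bayesian retinal decoding with fixational drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for Bayesian retinal decoding with fixational drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`retinacode` implements a complete desk-scale pipeline for asking how much of
a natural image is carried by the spike trains of a retinal ganglion cell
(RGC) population, and how fixational drift eye movements change that answer:

1. a synthetic stimulus generator (1/F textures, discretized Brownian drift,
   flashed and jittered movies with 120 Hz display timing and 1 ms spike
   bins);
2. a coupled Bernoulli GLM ("LNBRC") encoding model of RGC spiking with a
   network simulator and a FISTA-based maximum-likelihood fitter;
3. image priors (exact 1/F spectral Gaussian, general Fourier-diagonal
   Gaussian, and a trainable stand-in denoiser) behind a single
   `prior_step()` contract;
4. MAP image reconstruction by half-quadratic splitting, including joint
   inference of the image and an unknown eye trajectory with a particle
   filter EM; and
5. the evaluation toolbox (valid-region masks, shift-searched masked
   MS-SSIM, PSTHs, shift-predictor-corrected cross-correlograms, spike-time
   perturbation, repeat shuffling, drift-magnitude metrics).

Everything runs on synthetic retinas, so all claims are testable without
recorded data. This vignette documents the models, the defaults and their
units, the numerical choices, and what the synthetic world does and does not
establish.

# Encoding model

For cell $i$ with binary spike train $s_i[t]$ in 1 ms bins, the generator
signal is

$$g_i[t] = \mathbf{m}_i^\top \mathbf{v}[t-1] + (s_i \ast f_i)[t-1] +
\sum_{j \in N_i} (s_j \ast c_i^{(j)})[t-1] + b_i,$$

with a rank-1 (space $\times$ time separable) stimulus filter
$\mathbf{m}_i$, a strictly causal spike-history (feedback) kernel $f_i$,
coupling kernels $c_i^{(j)}$ to the neighbour set $N_i$, and a bias $b_i$.
Spiking is Bernoulli with probability $\sigma(g_i[t])$, giving the negative
log-likelihood $\sum_t [\log(1 + e^{g_i[t]}) - s_i[t] g_i[t]]$, jointly
convex in the parameters. All temporal kernels act on lags $\ge 1$ ms, so
the model is strictly causal; stimulus values enter as contrast (pixel
luminance minus the 0.5 gray background). The uncoupled variant (LNBR) drops
the coupling sum; the benchmark LNP model uses one bin per display frame and
an exponential nonlinearity with Poisson counts.

Neighbour sets follow a distance rule: any cell whose receptive-field center
lies within 2 (parasol) or 2.5 (midget) times the median nearest-neighbour
distance of the target cell's type.

## Bases

* Temporal stimulus kernel: 10 raised cosines, log-spaced over 1–250 ms.
* Feedback: 8 raised cosines over 1–100 ms; coupling: 4 over 1–50 ms.
  The log-stretch constant is 10 ms. These counts are conventional GLM
  practice; the source experiments do not print them.
* Spatial factor: an 8 × 8 tensor cubic B-spline grid over a crop of 1.8
  receptive-field radii around the center (simulator filters are stored on a
  2.5-radius crop). The knot spacing adapts to the crop. We chose a fixed
  function count rather than a fixed 2-pixel knot spacing because a 2 px
  grid over a parasol crop produces >100 coefficients per cell and does not
  fit the compute budget; 8 × 8 represents a difference-of-Gaussians
  receptive field to cosine similarity ≈ 0.98 while a 6 × 6 grid does not
  (≈ 0.8, which silently caps parameter recovery — measured, not guessed).

## Fitting

Because the stimulus filter is rank-1, fitting alternates two convex
problems: (spatial weights, feedback, coupling, bias) with the temporal
kernel fixed, then (temporal weights, feedback, coupling, bias) with the
spatial map fixed; two rounds by default. Each side is solved by FISTA with
backtracking line search and restart on objective increase, an L1 penalty on
the spatial spline coefficients and a group-L2,1 penalty on each neighbour's
coupling weights. The design matrix is held in single precision (the
optimizer tolerance, default relative objective change 1e-9, is far above
float rounding); reported objectives are accumulated in double and are
monotone across sides. After each round the spatial map is normalized to
unit L2 with the scale absorbed into the temporal factor, fixing the rank-1
gauge. Hyperparameters are chosen by `grid_search_hyperparams()`, which
mirrors the experimental procedure: fit a few cells of each type on a
training partition and keep the grid point with the lowest held-out NLL.

# Synthetic retina

`build_mosaic()` lays each of the four dominant RGC types (ON/OFF parasol,
ON/OFF midget) on an independent jittered hexagonal lattice; the RF radius
is half the lattice spacing, so neighbouring fields abut. Defaults are
peripheral-macaque-like: midget spacing 70 um, parasol 140 um, pixel pitch
11 um/px.

`sample_ground_truth_params()` draws encoder parameters in the span of the
fitting bases (so recovery experiments are well-posed):

* spatial: difference of Gaussians (center sigma = radius/2, surround twice
  as wide, half the volume), ON positive / OFF negative, scaled so flashed
  1/F textures drive the generator with standard deviation 2 log-odds units
  (chosen once as a realistic modulation: peak rates swing from the 20 Hz
  baseline to roughly 100–200 Hz, as natural-scene responses do);
* temporal: strongly biphasic (transient) kernels, midgets slower than
  parasols, normalized so the peak onset step response is 1;
* feedback: strongly negative at 1–5 ms (absolute refractoriness) with a
  weak tail to ~100 ms;
* coupling: small positive exponentials, homotypic neighbours 4 x stronger
  than heterotypic, amplitudes scaled by $1/\sqrt{|N_i|}$ so the network
  loop gain stays below 1 (without this the excitatory network saturates);
* bias: logit of the target unstimulated rate (default 20 Hz / 1000).

`simulate_spikes()` runs the network synchronously per 1 ms bin using only
bins $\le t-1$ (strictly causal); in "conditioned" mode the coupling term is
computed from supplied spike trains, as done when comparing model simulations
against recorded repeats. Network mode is an extension of that protocol (the
experiments condition coupling on recorded data); with coupling removed it
reduces exactly to independent per-cell simulation.

# Priors and the splitting loop

MAP reconstruction splits
$\arg\min_y \{-\log p(s \mid y) - \lambda \log p(y)\}$ into an encoding
sub-problem (convex, solved by L-BFGS; in closed form for the linearized
Gaussian likelihood and for the noiseless linear constraint) and a prior
sub-problem along an increasing log-spaced $\rho$ schedule (default 10
iterations). The prior step is:

* 1/F prior: exact per-frequency shrinkage
  $a_k \leftarrow a_k \, \rho / (\rho + 2\lambda/f_k^2)$ with radial
  frequency in cycles/image. The DC term is excluded (its $1/f^2$ weight
  would be infinite); mean luminance is left to the likelihood.
* Denoiser prior: one denoiser call at noise standard deviation
  $\sqrt{\lambda/\rho}$. The full-scale system conditions a deep CNN on the
  noise *variance* $\lambda/\rho$; denoisers are conventionally conditioned
  on the standard deviation, so we pass $\sqrt{\lambda/\rho}$ and note the
  interpretation.

The stand-in denoiser is a *learned spectral Wiener filter*: the mean signal
power spectrum of a >= 200-image 1/F texture corpus is estimated once, and
denoising applies gains $S(f)/(S(f) + \sigma^2)$, honouring the
(noisy, sigma, mask) contract, with invalid pixels mean-filled before
filtering. This replaces the deep CNN of the full-scale system (no deep
learning stack exists in the target environment); it is MSE-optimal for
stationary Gaussian signals, which 1/F textures are, and the plug-and-play
loop treats it as an opaque contract so a stronger model can be swapped in.

Plain half-quadratic splitting tracks the MAP with an $O(1/\rho)$ bias and
stalls once $\rho$ is large, so exact-prior soundness checks use the loop's
`dual = TRUE` variant (ADMM: a scaled dual variable and fixed $\rho$), which
converges to the exact MAP; with an overdetermined linearized likelihood ten
iterations reach RMSE < 1e-3 of the closed form. The default denoiser loop
keeps the paper-style schedule without a dual. Reconstructions are clipped
to [0, 1] only at the final output; flashed trials score the 150 ms window
from flash onset, drift trials the full 500 ms.

# Joint image and eye-trajectory estimation

Drift trials display the image shifted every 8.33 ms frame by a discretized
2D Brownian motion with diffusion constant D = 10 um^2/frame. We adopt the
eye-movement-literature convention MSD = 4Dt (per-axis increment variance
2D); the convention is a switch on `simulate_drift_trajectory()` since the
experiments print only "10 um^2/frame". Positions, not increments, are
rounded to integer pixels (ties toward zero) so rounding error does not
accumulate.

Joint estimation is MAP-EM: the image maximizes the particle-weighted
expected log posterior while a sequential importance resampling particle
filter (default N = 10 particles) re-estimates the trajectory once per frame
transition, with systematic resampling when the effective sample size falls
below N/2 and weights handled in the log domain. Images update once per 5
frame transitions. Three inference choices matter at desk scale and are our
own (the source's resampling details live in an unavailable supplement; its
variational family explicitly allows an arbitrary proposal):

* **Lookahead scoring.** Biphasic temporal kernels put almost no mass at
  lags < 10 ms, so the spike bins of frame f say nearly nothing about the
  position at frame f. Candidate positions are therefore scored on the bins
  of frames f..f+4, approximating the next few positions by the candidate
  (drift moves ~0.4 px per frame, so the approximation error is small).
  Without this the filter is effectively blind and tracking fails.
* **Likelihood-informed mixture proposals and a spread initial position.**
  Each particle proposes several transition draws and keeps one in
  proportion to its lookahead score (auxiliary SIR). The frame-1 position
  gets a 12 um prior spread because the current image estimate carries an
  arbitrary translation gauge.
* **Backward smoothing and a hard final M-step.** Filtering-only estimates
  ignore future spikes and suffer path degeneracy at small N; a standard
  backward (FFBS-style) pass over the stored filtering clouds — treating the
  emission as Markov in position, an approximation — yields the
  posterior-mean trajectory, and the final image is re-solved by a full
  splitting loop conditioned on that smoothed path. EM over (image,
  trajectory) is multi-modal at desk scale, so a small number of
  independently seeded chains is run and the chain with the lowest final
  spike NLL kept.

The absolute image position in joint mode is a gauge freedom; evaluation
resolves it by the shift search in `ms_ssim_masked()` and by mean-aligning
paths in `eye_position_error()`.

# Evaluation

Masked MS-SSIM uses the canonical 5-scale weights, truncated and
renormalized when the masked image is too small for 5 dyadic scales
(desk-scale images support 2–3), an 11-tap Gaussian window with
reduced-support normalization at borders, and maximization over integer
shifts for jointly estimated images. The valid region is the rasterized
convex hull of all receptive-field disks. PSTHs smooth 1 ms binned spikes
with a 2 ms Gaussian kernel and average over repeats. Cross-correlograms
subtract a shift predictor (cell b paired with the next repeat);
`shuffle_repeats()` permutes trials independently per cell, preserving every
per-cell marginal exactly while destroying noise correlations.
`perturb_spike_times()` jitters each spike independently (clipping to the
trial, collapsing same-bin collisions to keep trains binary and recording
the collapsed count). Realized drift magnitude is
$\sqrt{\mathrm{var}_x + \mathrm{var}_y}$ of the within-trial eye position (a
mean-per-axis-sd option exists).

# What the synthetic world establishes

The generator emulates: 1/F image statistics, mosaic geometry with abutting
receptive fields, transient center-surround responses, refractoriness, weak
homotypic coupling, Bernoulli spiking, and Brownian drift at the
experimental diffusion constant. It does not emulate photoreceptor noise,
nonlinear subunits, adaptation, drift persistence/self-avoidance, or eye
movements other than drift. A green acceptance suite therefore establishes
that the *algorithms* are sound and reproduce the qualitative phenomena
(joint > zero reconstruction, quality rising with drift magnitude, graded
degradation with spike-time jitter, signal- vs noise-correlation
separation) in a model-matched world — not that the quantitative MS-SSIM
levels of recorded retina are reproduced.

Desk-scale parameters differ from the full experiments in documented ways:
images 32–40 px across (not 256 x 160), ~40–120 cells (not ~700), a few
dozen trials per analysis (not thousands). At this information scale the
eye-position posterior is about a pixel wide, so the joint-vs-zero margin is
thinner than in the full-scale data; the acceptance tests compensate with
slightly more particles (15) and two EM restarts rather than by weakening
any threshold.

# Numerical choices and degenerate inputs

* Stable $\log(1+e^x)$ and sigmoid throughout; FISTA line search doubles the
  local Lipschitz estimate on failure and declares divergence past 1e18.
* Bin/frame alignment uses exact 25/3 ms frames: bin t belongs to frame
  floor((t-1)/8.33)+1; 60 frames = 500 bins exactly.
* `rho_schedule()` requires strictly increasing positive endpoints;
  `prior_step()` rejects rho <= 0; empty mosaics, singleton cell types, and
  non-binary spike trains raise invalid-argument errors.
* L1/L2,1 proximal maps produce exact zeros; a large group weight zeroes
  whole coupling groups exactly.
* The noiseless linear mode refuses ill-conditioned projection matrices
  (condition number > 1e8) naming the deficient cells.

# Known limitations

* The particle filter's lookahead weights reuse overlapping spike windows,
  so ensemble weights are modestly overconfident; resampling and smoothing
  absorb most of the effect, but calibrated posteriors over trajectories are
  not claimed.
* The backward smoother assumes Markov emissions; with ~30-frame temporal
  kernels this is an approximation.
* `fraction_psth_variance_explained()` is smoothing-limited at finite repeat
  counts: even the generating model does not reach 1 with a 2 ms kernel and
  tens of repeats.
* The Wiener stand-in denoiser cannot synthesize edges and textures the way
  a deep denoiser does, so absolute reconstruction quality is below what the
  full-scale system achieves with the same likelihood.
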