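## Sequential importance resampling particle filter over eye trajectories,
## and the joint image / eye-movement EM reconstruction.

#' Particle ensemble
#'
#' Weighted particles representing the posterior over eye-trajectory
#' prefixes. `states` holds the current positions (n x d, um); `paths` the
#' full per-particle history (frames x d x n); `log_w` the unnormalized log
#' weights (normalized weights in `$weights`).
#'
#' @param states n x d matrix of current particle states.
#' @param paths optional frames x d x n array of state histories.
#' @return list of class `particle_ensemble`.
#' @export
particle_ensemble <- function(states, paths = NULL) {
  n <- nrow(states)
  if (is.null(paths)) {
    paths <- aperm(array(states, c(n, ncol(states), 1)), c(3, 2, 1))
  }
  structure(list(states = states, paths = paths,
                 log_w = rep(0, n), weights = rep(1 / n, n)),
            class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf("<particle_ensemble> %d particles, %d frames, ESS %.2f\n",
              nrow(x$states), dim(x$paths)[1], particle_ess(x)))
  invisible(x)
}

#' Effective sample size of a particle ensemble
#' @param ensemble a `particle_ensemble`.
#' @return scalar in `[1, n]`.
#' @export
particle_ess <- function(ensemble) 1 / sum(ensemble$weights^2)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' One sequential-importance-resampling update
#'
#' Propagates every particle through the transition kernel, multiplies its
#' weight by the observation likelihood (computed in the log domain with
#' max-subtraction), renormalizes, and applies systematic resampling when the
#' effective sample size drops below `resample_frac * n`.
#'
#' @param ensemble a [particle_ensemble()].
#' @param propagate_fn function(states) -> new states (n x d); the Brownian
#'   transition draw in the eye-movement case.
#' @param loglik_fn function(states, ensemble) -> per-particle log-likelihood
#'   of the new observation.
#' @param resample_frac resampling trigger as a fraction of n (default 0.5).
#' @return updated `particle_ensemble` (weights normalized; `$resampled`
#'   flags whether resampling occurred, `$ancestors` gives the resampled
#'   ancestor indices).
#' @export
particle_filter_update <- function(ensemble, propagate_fn, loglik_fn,
                                   resample_frac = 0.5) {
  new_states <- propagate_fn(ensemble$states)
  d <- ncol(new_states); n <- nrow(new_states)
  paths <- array(0, c(dim(ensemble$paths)[1] + 1, d, n))
  paths[seq_len(dim(ensemble$paths)[1]), , ] <- ensemble$paths
  paths[dim(paths)[1], , ] <- t(new_states)
  ll <- loglik_fn(new_states, ensemble)
  if (all(!is.finite(ll))) {
    stop("particle likelihood underflow: all weights zero/NaN", call. = FALSE)
  }
  log_w <- ensemble$log_w + ll
  log_w <- log_w - logsumexp(log_w)   # max-subtracted normalization
  w <- exp(log_w)
  w <- w / sum(w)
  out <- structure(list(states = new_states, paths = paths,
                        log_w = log_w, weights = w,
                        resampled = FALSE, ancestors = seq_len(n)),
                   class = "particle_ensemble")
  if (1 / sum(w^2) < resample_frac * n) {
    anc <- systematic_resample(w)
    out$states <- new_states[anc, , drop = FALSE]
    out$paths <- paths[, , anc, drop = FALSE]
    out$log_w <- rep(0, n)
    out$weights <- rep(1 / n, n)
    out$resampled <- TRUE
    out$ancestors <- anc
  }
  out
}

systematic_resample <- function(w) {
  n <- length(w)
  u <- (runif(1) + 0:(n - 1)) / n
  findInterval(u, cumsum(w)) + 1L
}

#' Posterior-mean trajectory of an ensemble
#' @param ensemble a `particle_ensemble`.
#' @return frames x d matrix (um).
#' @export
posterior_mean_path <- function(ensemble) {
  Fn <- dim(ensemble$paths)[1]; d <- dim(ensemble$paths)[2]
  out <- matrix(0, Fn, d)
  for (k in seq_len(dim(ensemble$paths)[3])) {
    out <- out + ensemble$weights[k] * ensemble$paths[, , k]
  }
  out
}

# projection of shifted-image contrast onto all cells, cached by offset
# (cache valid while the image is unchanged)
cached_projection <- function(ctx, y, offset, cache) {
  key <- paste(offset[1], offset[2])
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  ysh <- if (all(offset == 0)) y else shift_image(y, offset)
  p <- as.numeric(ctx$W %*% (as.numeric(ysh) - BACKGROUND_GRAY))
  cache[[key]] <- p
  p
}

#' Forward-filtering backward-smoothing marginal weights
#'
#' Given per-frame filtering clouds (particle states and weights) under a
#' Gaussian random-walk transition, computes the marginal smoothing weights
#' by the standard backward recursion and returns the posterior-mean
#' smoothed path. The spike likelihood is treated as Markov in the eye
#' position (the temporal kernels concentrate most stimulus weight within a
#' few frames), a documented approximation.
#'
#' @param clouds list per frame: `list(states = N x d, weights)`.
#' @param step_sd per-axis transition standard deviation.
#' @return frames x d matrix of posterior-mean smoothed positions.
#' @export
smooth_particle_path <- function(clouds, step_sd) {
  Tn <- length(clouds)
  d <- ncol(clouds[[1]]$states)
  sw <- vector("list", Tn)
  sw[[Tn]] <- clouds[[Tn]]$weights
  for (t in (Tn - 1):1) {
    st <- clouds[[t]]$states
    st1 <- clouds[[t + 1]]$states
    wt <- clouds[[t]]$weights
    # trans[j, i] = p(x_{t+1, j} | x_{t, i})
    trans <- matrix(0, nrow(st1), nrow(st))
    for (j in seq_len(nrow(st1))) {
      dif <- sweep(st, 2, st1[j, ])
      trans[j, ] <- exp(-rowSums(dif^2) / (2 * step_sd^2))
    }
    denom <- as.numeric(trans %*% wt)
    denom[denom <= 0] <- .Machine$double.xmin
    sw[[t]] <- wt * as.numeric(t(trans / denom) %*% sw[[t + 1]])
    s <- sum(sw[[t]])
    sw[[t]] <- if (s > 0) sw[[t]] / s else rep(1 / length(wt), length(wt))
  }
  out <- matrix(0, Tn, d)
  for (t in seq_len(Tn)) {
    out[t, ] <- as.numeric(sw[[t]] %*% clouds[[t]]$states)
  }
  out
}

#' Joint estimation of the image and the eye trajectory (MAP-EM)
#'
#' Initializes the image by ten splitting iterations assuming a fixed eye at
#' the origin; then runs a particle filter (default N = 10 particles,
#' likelihood-informed mixture proposals with `n_propose` transition draws
#' per particle; the variational family allows an arbitrary proposal) over
#' eye positions, updated at every display frame transition, interleaving an
#' image update (one encoding step on the particle-weighted expected NLL
#' plus one prior step) every `update_every` frame transitions along an
#' increasing rho schedule. The trajectory estimate is then refined by
#' backward smoothing of the filtering clouds, and the final image is
#' reconstructed by a full splitting loop conditioned on the smoothed
#' posterior-mean trajectory (hard M-step).
#'
#' @param spikes observed `spike_trains` over the drift trial.
#' @param encoder `rgc_encoder`.
#' @param prior image prior.
#' @param timing [trial_timing()] of kind `"drift"`.
#' @param schedule rho schedule for the sweep's image updates.
#' @param final_schedule rho schedule for the final conditioned splitting
#'   loop.
#' @param lambda prior weight.
#' @param n_particles particle count (default 10).
#' @param update_every image update cadence in frame transitions (default 5).
#' @param diffusion_um2_per_frame Brownian transition diffusion constant.
#' @param init_schedule rho schedule for the zero-movement initialization
#'   (default 10 iterations).
#' @param n_propose transition draws per particle per frame for the
#'   likelihood-informed mixture proposal (default 8).
#' @param lookahead frames of spikes ahead of the transition used to score
#'   candidate positions (default 4; the candidate position stands in for
#'   the next few positions, a documented approximation).
#' @param init_spread_um prior spread of the frame-1 position relative to
#'   the current image (translation gauge; default 12 um).
#' @param n_restarts independently seeded EM chains; the chain with the
#'   lowest final spike NLL is returned (default 2).
#' @param n_em outer EM iterations: each re-runs the particle filter against
#'   the current image, re-smooths, and re-solves the conditioned splitting
#'   loop (default 2; mid-trial image updates happen only in the first).
#' @param mask optional valid-region mask.
#' @param maxit_encoding L-BFGS cap per encoding step.
#' @param seed RNG seed for particle proposals.
#' @return a `recon_result` with `$trajectory` (smoothed posterior-mean
#'   path, um) and `$ensemble` (final filtering ensemble).
#' @export
reconstruct_joint_em <- function(spikes, encoder, prior,
                                 timing = trial_timing("drift"),
                                 schedule = NULL,
                                 final_schedule = rho_schedule(0.3, 30, 10),
                                 lambda = 1,
                                 n_particles = 10, update_every = 5,
                                 diffusion_um2_per_frame = 10,
                                 init_schedule = rho_schedule(0.1, 2, 10),
                                 n_propose = 8, lookahead = 4, n_em = 2,
                                 init_spread_um = 12, n_restarts = 2,
                                 mask = NULL,
                                 maxit_encoding = 15, seed = NULL,
                                 .ctx = NULL, .init_image = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  ctx <- .ctx %||% recon_context(encoder, spikes, timing)
  if (n_restarts > 1) {
    # EM over image and trajectory is multi-modal at this scale: run a few
    # independently seeded EM chains (sharing the deterministic zero-movement
    # initialization) and keep the one with the lowest final spike NLL under
    # its own (image, trajectory) pair
    init0 <- run_splitting_loop(ctx, prior, init_schedule, lambda,
                                mask = mask,
                                maxit_encoding = maxit_encoding)
    runs <- lapply(seq_len(n_restarts), function(r) {
      reconstruct_joint_em(spikes, encoder, prior, timing, schedule,
                           final_schedule, lambda, n_particles, update_every,
                           diffusion_um2_per_frame, init_schedule, n_propose,
                           lookahead, n_em, init_spread_um, n_restarts = 1,
                           mask = mask, maxit_encoding = maxit_encoding,
                           seed = NULL, .ctx = ctx, .init_image = init0)
    })
    pitch0 <- encoder$geometry$pixel_pitch_um
    nlls <- vapply(runs, function(r) {
      tp <- round_half_toward_zero(r$trajectory / pitch0)
      recon_nll_grad(ctx, r$image, list(tp), 1, grad = FALSE)$nll
    }, 0)
    best <- runs[[which.min(nlls)]]
    best$config$restart_nll <- nlls
    return(best)
  }
  pitch <- encoder$geometry$pixel_pitch_um
  n_frames <- timing$n_frames
  n_updates <- max(1, floor((n_frames - 1) / update_every))
  if (is.null(schedule)) schedule <- rho_schedule(0.3, 5, n_updates)
  if (length(schedule) < n_updates) {
    schedule <- rep(schedule, length.out = n_updates)
  }

  ## initialization: fixed eye at the origin, ten alternating iterations
  init <- .init_image %||% run_splitting_loop(ctx, prior, init_schedule,
                                              lambda, mask = mask,
                                              maxit_encoding = maxit_encoding)
  y <- init$image
  trace <- init$trace
  step_sd <- sqrt(2 * diffusion_um2_per_frame)
  fob <- frame_of_bin(timing$n_bins, timing$frame_period_ms)
  upd <- 0
  smoothed <- NULL

  for (em in seq_len(n_em)) {
  # coarse-to-fine: the first tracking sweep runs against a lightly blurred
  # image, widening the likelihood basin and discounting fine structure the
  # zero-movement initialization got wrong; later sweeps use full resolution
  y_track <- if (em == 1 && n_em > 1) {
    filter2_sep(y, gaussian_kernel_1d(1, radius = 3))
  } else y
  # the current image carries an arbitrary translation gauge (it inherits
  # the mean offset of whatever trajectory hypothesis produced it), so the
  # frame-1 position is itself uncertain: spread the initial particles and
  # weight them by the first lookahead window
  st0 <- matrix(rnorm(2 * n_particles, sd = init_spread_um), n_particles)
  st0[1, ] <- 0
  cache <- new.env(parent = emptyenv())
  Phist <- array(0, c(ctx$n_cells, n_frames, n_particles))
  fob0 <- frame_of_bin(timing$n_bins, timing$frame_period_ms)
  bins0 <- intersect(which(fob0 <= 1 + lookahead), timing$window_bins)
  sb0 <- ctx$s[, bins0, drop = FALSE]
  K0 <- t(apply(ctx$Karr[bins0, seq_len(1 + lookahead), , drop = FALSE], 3,
                rowSums))
  ll0 <- vapply(seq_len(n_particles), function(k) {
    o <- round_half_toward_zero(st0[k, ] / pitch)
    p <- cached_projection(ctx, y_track, o, cache)
    Phist[, 1, k] <<- p
    cpp_bernoulli_ll(ctx$h[, bins0, drop = FALSE] + K0 * p, sb0)
  }, 0)
  ens <- particle_ensemble(st0)
  ens$log_w <- ll0 - logsumexp(ll0)
  ens$weights <- exp(ens$log_w)
  ens$weights <- ens$weights / sum(ens$weights)
  clouds <- vector("list", n_frames)
  clouds[[1]] <- list(states = ens$states, weights = ens$weights)
  newproj <- matrix(0, ctx$n_cells, n_particles)

  for (f in 2:n_frames) {
    # lookahead window: the biphasic temporal kernels place little mass at
    # lags < 10 ms, so the bins of frame f alone say almost nothing about
    # the position at frame f; scoring candidates on the bins of frames
    # f..f+lookahead (approximating those positions by the candidate, valid
    # because drift moves ~0.4 px per frame) makes the update informative
    f_hi <- min(f + lookahead, n_frames)
    bins <- intersect(which(fob >= f & fob <= f_hi), timing$window_bins)
    sb <- ctx$s[, bins, drop = FALSE]
    # summed kernel weight of frames f..f_hi at these bins, per cell
    Kf <- t(apply(ctx$Karr[bins, f:f_hi, , drop = FALSE], 3, rowSums))
    if (length(bins) == 1) Kf <- matrix(Kf, ncol = 1)
    gh_all <- cpp_pf_history_drive(ctx$Karr, Phist, ctx$h, bins, f - 1)
    n <- nrow(ens$states)
    new_states <- matrix(0, n, 2)
    incr <- numeric(n)
    for (k in seq_len(n)) {
      gh <- matrix(gh_all[, , k], ctx$n_cells)
      # likelihood-informed mixture proposal: several transition draws,
      # select one in proportion to the new frame's likelihood, and weight
      # by the mean candidate likelihood (auxiliary SIR)
      cand <- matrix(ens$states[k, ], n_propose, 2, byrow = TRUE) +
        matrix(rnorm(2 * n_propose, sd = step_sd), n_propose)
      ll <- vapply(seq_len(n_propose), function(m) {
        o <- round_half_toward_zero(cand[m, ] / pitch)
        p <- cached_projection(ctx, y_track, o, cache)
        cpp_bernoulli_ll(gh + Kf * p, sb)
      }, 0)
      pick <- sample.int(n_propose, 1, prob = exp(ll - max(ll)))
      new_states[k, ] <- cand[pick, ]
      incr[k] <- logsumexp(ll) - log(n_propose)
      newproj[, k] <- cached_projection(
        ctx, y_track, round_half_toward_zero(cand[pick, ] / pitch), cache)
    }
    paths <- array(0, c(f, 2, n))
    paths[seq_len(f - 1), , ] <- ens$paths
    paths[f, , ] <- t(new_states)
    log_w <- ens$log_w + incr
    log_w <- log_w - logsumexp(log_w)
    w <- exp(log_w); w <- w / sum(w)
    ens <- structure(list(states = new_states, paths = paths,
                          log_w = log_w, weights = w,
                          resampled = FALSE, ancestors = seq_len(n)),
                     class = "particle_ensemble")
    Phist[, f, ] <- newproj
    clouds[[f]] <- list(states = new_states, weights = w)
    if (1 / sum(w^2) < n / 2) {
      anc <- systematic_resample(w)
      ens$states <- new_states[anc, , drop = FALSE]
      ens$paths <- paths[, , anc, drop = FALSE]
      ens$log_w <- rep(0, n); ens$weights <- rep(1 / n, n)
      ens$resampled <- TRUE; ens$ancestors <- anc
      Phist <- Phist[, , anc, drop = FALSE]
    }

    if (em == 1 && (f - 1) %% update_every == 0 && upd < n_updates) {
      upd <- upd + 1
      rho <- schedule[upd]
      trajs <- lapply(seq_len(n_particles), function(k) {
        offs <- round_half_toward_zero(matrix(ens$paths[, , k],
                                              ncol = 2) / pitch)
        rbind(offs, matrix(0L, n_frames - f, 2))
      })
      st <- encoding_step(ctx, y, rho, trajs = trajs, wts = ens$weights,
                          init = y, maxit = maxit_encoding, max_frame = f)
      y <- prior_step(prior, st$x, rho, lambda, mask = mask)
      trace <- c(trace, st$value)
      # image changed: refresh caches and the projection history
      cache <- new.env(parent = emptyenv())
      for (k in seq_len(n_particles)) {
        offs <- round_half_toward_zero(matrix(ens$paths[, , k],
                                              ncol = 2) / pitch)
        for (ff in seq_len(f)) {
          Phist[, ff, k] <- cached_projection(ctx, y, offs[ff, ], cache)
        }
      }
    }
  }

  ## backward smoothing of the filtering clouds, then a final splitting loop
  ## conditioned on the smoothed posterior-mean trajectory
  smoothed <- smooth_particle_path(clouds, step_sd)
  final_traj <- round_half_toward_zero(smoothed / pitch)
  # intermediate EM iterations keep the image moderately coupled so the next
  # tracking sweep is not locked to a possibly wrong hypothesis; only the
  # last iteration runs the schedule out to its sharp endpoint
  sched_em <- if (em < n_em) {
    final_schedule[final_schedule <= median(final_schedule)]
  } else final_schedule
  fin <- run_splitting_loop(ctx, prior, sched_em, lambda,
                            trajs = list(final_traj), wts = 1, mask = mask,
                            maxit_encoding = maxit_encoding, z0 = y)
  y <- fin$image
  trace <- c(trace, fin$trace)
  }
  recon_result(pmin(pmax(y, 0), 1), trace,
               trajectory = smoothed, ensemble = ens,
               config = list(mode = "joint", n_particles = n_particles,
                             update_every = update_every,
                             n_propose = n_propose,
                             diffusion = diffusion_um2_per_frame))
}
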