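## Bernoulli spike-train simulation from an LNBRC encoder.
##
## Spiking is strictly causal: the probability of a spike in 1 ms bin t
## depends on the stimulus shown during bins <= t-1 and on spikes in bins
## <= t-1. In "network" mode all cells are simulated jointly and coupling
## reads the simulated spikes of neighbours; in "conditioned" mode coupling
## reads a provided (e.g. recorded) spike train set, as done when evaluating
## model fit against data.

#' Per-cell stimulus contrast projections at frame resolution
#'
#' Projects every display frame (minus the 0.5 gray background) onto each
#' cell's cropped spatial filter. For drift stimuli the image is shifted by
#' the trajectory's integer offsets before cropping.
#'
#' @param encoder an `rgc_encoder`.
#' @param stimulus a `stim_movie`, `flashed_stimulus_set` or
#'   `drift_stimulus_set`.
#' @return list with `proj` (cells x total frames), `frame_period_ms`,
#'   `n_bins`, `n_frames`.
#' @export
stimulus_projection <- function(encoder, stimulus) {
  cells <- encoder$cells
  if (inherits(stimulus, "stim_movie")) {
    fr <- stimulus$frames
    nF <- dim(fr)[3]
    proj <- matrix(0, length(cells), nF)
    for (i in seq_along(cells)) {
      cl <- cells[[i]]
      for (f in seq_len(nF)) {
        proj[i, f] <- sum(cl$spatial *
                            (fr[cl$crop_rows, cl$crop_cols, f] - BACKGROUND_GRAY))
      }
    }
    fp <- stimulus$frame_period_ms
  } else if (inherits(stimulus, "flashed_stimulus_set")) {
    n_img <- length(stimulus$images)
    # projections of each distinct image per cell
    pimg <- matrix(0, length(cells), n_img)
    for (i in seq_along(cells)) {
      cl <- cells[[i]]
      for (k in seq_len(n_img)) {
        img <- unclass(stimulus$images[[k]])
        pimg[i, k] <- sum(cl$spatial *
                            (img[cl$crop_rows, cl$crop_cols] - BACKGROUND_GRAY))
      }
    }
    fpt <- stimulus$n_frames_per_trial
    proj <- matrix(0, length(cells), n_img * fpt)
    for (k in seq_len(n_img)) {
      cols <- (k - 1) * fpt + stimulus$flash_frames
      proj[, cols] <- pimg[, k]
    }
    fp <- stimulus$frame_period_ms
  } else if (inherits(stimulus, "drift_stimulus_set")) {
    fpt <- stimulus$n_frames_per_trial
    n_tr <- length(stimulus$images)
    proj <- matrix(0, length(cells), n_tr * fpt)
    for (k in seq_len(n_tr)) {
      img <- unclass(stimulus$images[[k]])
      px <- stimulus$trajectories[[k]]$displacements_px
      for (f in seq_len(fpt)) {
        shifted <- shift_image(img, px[f, ])
        for (i in seq_along(cells)) {
          cl <- cells[[i]]
          proj[i, (k - 1) * fpt + f] <-
            sum(cl$spatial * (shifted[cl$crop_rows, cl$crop_cols] - BACKGROUND_GRAY))
        }
      }
    }
    fp <- stimulus$frame_period_ms
  } else {
    stop_invalid("unsupported stimulus class: %s", class(stimulus)[1])
  }
  list(proj = proj, frame_period_ms = fp, n_frames = ncol(proj),
       n_bins = bins_for_frames(ncol(proj), fp))
}

# strictly causal convolution: y[t] = sum_{tau>=1} k[tau] x[t - tau]
conv_causal <- function(x, k) {
  T <- length(x); L <- length(k)
  n <- stats::nextn(T + L + 1)
  xf <- fft(c(x, numeric(n - T)))
  kf <- fft(c(0, k, numeric(n - L - 1)))
  Re(fft(xf * kf, inverse = TRUE))[seq_len(T)] / n
}

# y[t] = sum_{tau>=1} K[tau, j] s[t - tau] for a sparse binary s
spike_basis_conv <- function(spike_idx, K, T) {
  out <- matrix(0, T, ncol(K))
  if (length(spike_idx) == 0) return(out)
  for (j in seq_len(ncol(K))) {
    col <- numeric(T)
    for (tau in seq_len(nrow(K))) {
      w <- K[tau, j]
      if (w == 0) next
      idx <- spike_idx + tau
      idx <- idx[idx <= T]
      if (length(idx)) col[idx] <- col[idx] + w
    }
    out[, j] <- col
  }
  out
}

#' Stimulus drive of the generator signal (cells x 1 ms bins)
#'
#' The rank-1 stimulus term of the LNBRC generator signal: per-frame contrast
#' projections upsampled to 1 ms and convolved (strictly causally) with each
#' cell's temporal kernel.
#'
#' @inheritParams stimulus_projection
#' @return matrix cells x bins.
#' @export
stimulus_drive <- function(encoder, stimulus) {
  sp <- stimulus_projection(encoder, stimulus)
  fob <- frame_of_bin(sp$n_bins, sp$frame_period_ms)
  drive <- matrix(0, length(encoder$cells), sp$n_bins)
  for (i in seq_along(encoder$cells)) {
    z <- sp$proj[i, fob]
    drive[i, ] <- conv_causal(z, encoder$cells[[i]]$temporal)
  }
  drive
}

#' Simulate LNBRC spike trains
#'
#' Per 1 ms bin, each cell spikes with probability
#' `sigmoid(g_i[t])` where the generator signal `g` sums the stimulus drive,
#' feedback from the cell's own (simulated) past spikes, coupling from
#' neighbours' past spikes, and the bias.
#'
#' @param encoder an `rgc_encoder` (ground truth or fitted).
#' @param stimulus a stimulus object accepted by [stimulus_projection()].
#' @param mode `"network"`: all cells simulated jointly, coupling reads the
#'   simulated spikes. `"conditioned"`: coupling reads `conditioning_spikes`
#'   (feedback still reads the cell's own simulated spikes).
#' @param seed integer seed.
#' @param conditioning_spikes `spike_trains` required in conditioned mode.
#' @return a [spike_trains()] matrix (cells x bins).
#' @export
simulate_spikes <- function(encoder, stimulus,
                            mode = c("network", "conditioned"),
                            seed = NULL, conditioning_spikes = NULL) {
  mode <- match.arg(mode)
  if (mode == "conditioned" && is.null(conditioning_spikes)) {
    stop_invalid("conditioned mode requires 'conditioning_spikes'")
  }
  drive <- stimulus_drive(encoder, stimulus)
  T <- ncol(drive)
  Lmem <- length(encoder$cells[[1]]$temporal)
  if (T < Lmem) {
    stop_invalid("stimulus duration (%d ms) shorter than filter memory (%d ms)",
                 T, Lmem)
  }
  n <- length(encoder$cells)
  bias <- vapply(encoder$cells, `[[`, 0, "bias")
  fbL <- length(encoder$cells[[1]]$feedback)
  fb <- t(vapply(encoder$cells, `[[`, numeric(fbL), "feedback"))
  # coupling pairs
  src <- integer(0); dst <- integer(0); ckern <- NULL
  ids <- vapply(encoder$cells, `[[`, 0, "cell_id")
  for (i in seq_len(n)) {
    cl <- encoder$cells[[i]]
    for (k in seq_along(cl$neighbors)) {
      j <- match(cl$neighbors[k], ids)
      src <- c(src, j); dst <- c(dst, i)
      ckern <- rbind(ckern, cl$coupling[[k]])
    }
  }
  if (is.null(ckern)) ckern <- matrix(0, 0, 1)
  if (mode == "conditioned" && length(src) > 0) {
    # coupling contribution is a fixed convolution of the provided spikes
    for (p in seq_along(src)) {
      sidx <- which(conditioning_spikes[src[p], ] == 1)
      add <- spike_basis_conv(sidx, matrix(ckern[p, ], ncol = 1), T)
      drive[dst[p], ] <- drive[dst[p], ] + add[, 1]
    }
    src <- integer(0); dst <- integer(0); ckern <- matrix(0, 0, 1)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  sim <- cpp_simulate_lnbrc(drive, bias, fb, src - 1L, dst - 1L, ckern)
  spike_trains(sim, cell_ids = ids)
}

#' Simulate repeated trials of the same stimulus
#' @inheritParams simulate_spikes
#' @param n_repeats number of repeats.
#' @return list of `spike_trains`, one per repeat.
#' @export
simulate_repeats <- function(encoder, stimulus, n_repeats, seed = 1,
                             mode = "network", conditioning_spikes = NULL) {
  set.seed(as.integer(seed))
  lapply(seq_len(n_repeats), function(r) {
    simulate_spikes(encoder, stimulus, mode = mode,
                    conditioning_spikes = conditioning_spikes)
  })
}
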