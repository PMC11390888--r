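## Encoding likelihoods: the LNBRC / LNBR Bernoulli negative log-likelihood
## at 1 ms resolution and the benchmark LNP Poisson negative log-likelihood
## at one-bin-per-frame resolution.

#' LNBRC generator signal
#'
#' `g_i[t] = m_i' v[t-1] + (s_i * f_i)[t-1] + sum_j (s_j * c_i^(j))[t-1] + b_i`:
#' the strictly causal sum of the filtered stimulus, filtered own spikes,
#' filtered neighbour spikes, and the bias. All kernels act on lags >= 1 ms.
#'
#' @param encoder an `rgc_encoder`.
#' @param stimulus stimulus object (see [stimulus_projection()]).
#' @param spikes a `spike_trains` matrix covering all cells of the encoder.
#' @param cell `cell_id` of the target cell.
#' @param t_range integer bin range (default: all bins). Bins before the
#'   recording start are an error.
#' @param include_coupling set FALSE for the uncoupled (LNBR) generator.
#' @return numeric vector `g` over `t_range`.
#' @export
generator_signal <- function(encoder, stimulus, spikes, cell, t_range = NULL,
                             include_coupling = TRUE) {
  ids <- vapply(encoder$cells, `[[`, 0, "cell_id")
  i <- match(cell, ids)
  if (is.na(i)) stop_invalid("cell %s not in encoder", format(cell))
  cl <- encoder$cells[[i]]
  T <- ncol(spikes)
  if (is.null(t_range)) t_range <- seq_len(T)
  if (min(t_range) < 1 || max(t_range) > T) {
    stop_invalid("t_range [%d, %d] extends beyond available history [1, %d]",
                 min(t_range), max(t_range), T)
  }
  sp <- stimulus_projection(encoder, stimulus)
  if (sp$n_bins < T) {
    stop_invalid("spike trains (%d bins) longer than stimulus (%d bins)",
                 T, sp$n_bins)
  }
  fob <- frame_of_bin(T, sp$frame_period_ms)
  z <- sp$proj[i, fob]
  g <- conv_causal(z, cl$temporal) + cl$bias
  # the spike matrix may cover more cells than the encoder: match by id
  own_row <- match(cell, attr(spikes, "cell_ids")) %||% i
  if (is.na(own_row)) own_row <- i
  own_idx <- which(spikes[own_row, ] == 1)
  g <- g + spike_basis_conv(own_idx, matrix(cl$feedback, ncol = 1), T)[, 1]
  if (include_coupling && length(cl$neighbors) > 0) {
    rows <- match(cl$neighbors, attr(spikes, "cell_ids"))
    for (k in seq_along(cl$neighbors)) {
      sidx <- which(spikes[rows[k], ] == 1)
      g <- g + spike_basis_conv(sidx, matrix(cl$coupling[[k]], ncol = 1), T)[, 1]
    }
  }
  g[t_range]
}

#' Bernoulli encoding negative log-likelihoods (LNBRC and uncoupled LNBR)
#'
#' `sum_t [log(1 + exp(g[t])) - s[t] * g[t]]`, computed in a numerically
#' stable form. `lnbr_nll()` is the same objective with the coupling filters
#' removed.
#'
#' @inheritParams generator_signal
#' @return scalar negative log-likelihood.
#' @export
lnbrc_nll <- function(encoder, stimulus, spikes, cell, t_range = NULL,
                      include_coupling = TRUE) {
  if (!all(spikes %in% c(0, 1))) stop_invalid("spike trains must be binary")
  T <- ncol(spikes)
  if (is.null(t_range)) t_range <- seq_len(T)
  g <- generator_signal(encoder, stimulus, spikes, cell, t_range,
                        include_coupling = include_coupling)
  row <- match(cell, attr(spikes, "cell_ids"))
  if (is.na(row)) stop_invalid("cell %s not in spike trains", format(cell))
  s <- spikes[row, t_range]
  sum(log1pexp(g) - s * g)
}

#' @rdname lnbrc_nll
#' @export
lnbr_nll <- function(encoder, stimulus, spikes, cell, t_range = NULL) {
  lnbrc_nll(encoder, stimulus, spikes, cell, t_range,
            include_coupling = FALSE)
}

#' Single-cell LNP parameters
#'
#' The benchmark linear-nonlinear-Poisson model: spikes counted in one bin
#' per display frame, exponential nonlinearity, generator
#' `g[f] = m' v[f] + b` where the temporal kernel acts on frame lags >= 0
#' (the current frame is included).
#'
#' @param crop_rows,crop_cols spatial crop.
#' @param spatial spatial filter matrix over the crop.
#' @param temporal_frames kernel over frame lags `0..L-1`.
#' @param bias additive constant (log spikes/frame).
#' @return list of class `lnp_cell`.
#' @export
lnp_cell <- function(crop_rows, crop_cols, spatial, temporal_frames, bias) {
  structure(list(crop_rows = crop_rows, crop_cols = crop_cols,
                 spatial = spatial, temporal_frames = temporal_frames,
                 bias = bias),
            class = "lnp_cell")
}

#' LNP generator signal and Poisson negative log-likelihood
#'
#' `sum_f [exp(g[f]) - g[f] * s[f]]` with frame-binned counts `s`.
#'
#' @param params an [lnp_cell()].
#' @param frame_proj numeric vector of per-frame contrast projections of the
#'   stimulus onto `params$spatial` (see [stimulus_projection()]).
#' @param counts nonnegative integer spike counts, one per frame.
#' @return scalar negative log-likelihood.
#' @export
lnp_nll <- function(params, frame_proj, counts) {
  if (any(counts < 0)) stop_invalid("spike counts must be nonnegative")
  g <- lnp_generator(params, frame_proj)
  sum(exp(g) - g * counts)
}

#' @rdname lnp_nll
#' @export
lnp_generator <- function(params, frame_proj) {
  k <- params$temporal_frames
  F <- length(frame_proj)
  g <- numeric(F)
  for (tau in seq_along(k)) {          # lag tau - 1 (current frame included)
    idx <- seq_len(F - tau + 1)
    g[idx + tau - 1] <- g[idx + tau - 1] + k[tau] * frame_proj[idx]
  }
  g + params$bias
}

#' Bin 1 ms spike trains into per-frame counts
#' @param spikes a `spike_trains` matrix.
#' @param frame_period_ms display frame duration.
#' @return matrix cells x frames of counts.
#' @export
bin_spikes_per_frame <- function(spikes, frame_period_ms = DEFAULT_FRAME_PERIOD_MS) {
  fob <- frame_of_bin(ncol(spikes), frame_period_ms)
  t(apply(spikes, 1, function(s) tapply(s, fob, sum)))
}
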