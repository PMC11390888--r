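## LNBRC encoder parameter containers and synthetic ground-truth generation.
##
## An encoder holds, per cell: a cropped spatial filter, a 1 ms-resolution
## temporal stimulus kernel, a strictly causal feedback (spike-history)
## kernel, coupling kernels to neighbouring cells, and a bias. The stimulus
## filter is rank-1 (space x time separable). Kernels act on stimulus
## *contrast* (pixel value minus the 0.5 background).

#' Default temporal basis set for LNBRC filters
#'
#' 10 stimulus-temporal raised cosines over 1-250 ms, 8 feedback bases over
#' 1-100 ms, 4 coupling bases over 1-50 ms, log stretch 10 ms.
#' @return list with elements `temporal`, `feedback`, `coupling`
#'   ([raised_cosine_basis] matrices) and `spatial_n` (spline functions per
#'   dimension, default 8).
#' @export
default_basis_set <- function() {
  list(temporal = raised_cosine_basis(10, 1, 250, log_stretch = 10),
       feedback = raised_cosine_basis(8, 1, 100, log_stretch = 10),
       coupling = raised_cosine_basis(4, 1, 50, log_stretch = 10),
       spatial_n = 8)
}

#' Encoder geometry: how mosaic microns map onto image pixels
#'
#' Pixel `(r, c)` is centered at `((r - 0.5) * pitch, (c - 0.5) * pitch)` um.
#' @param height,width image size in pixels.
#' @param pixel_pitch_um microns per pixel.
#' @return list of class `encoder_geometry`.
#' @export
encoder_geometry <- function(height, width,
                             pixel_pitch_um = DEFAULT_PIXEL_PITCH_UM) {
  structure(list(height = height, width = width,
                 pixel_pitch_um = pixel_pitch_um),
            class = "encoder_geometry")
}

um_to_px <- function(um, geom) um / geom$pixel_pitch_um + 0.5

#' Crop window around a receptive field
#'
#' Rectangular crop of `crop_factor` times the RF radius on each side of the
#' center, clipped to the image.
#' @keywords internal
rf_crop <- function(center_px, radius_px, geom, crop_factor = 2.5) {
  half <- max(2, ceiling(crop_factor * radius_px))
  rows <- max(1, round(center_px[1]) - half):min(geom$height, round(center_px[1]) + half)
  cols <- max(1, round(center_px[2]) - half):min(geom$width, round(center_px[2]) + half)
  list(rows = rows, cols = cols)
}

#' Sample ground-truth LNBRC parameters for a mosaic
#'
#' Spatial filters are difference-of-Gaussians at the RF center (center sigma
#' = radius / 2, surround sigma 2x wider, surround weight 0.5 of the center
#' volume), positive for ON and negative for OFF cells, normalized to unit L2
#' and scaled so that flashed 1/F textures drive the generator signal with a
#' target standard deviation. Temporal kernels are biphasic (transient);
#' feedback kernels are strongly negative at short lags (refractoriness);
#' coupling kernels are small, positive, and strongest between homotypic
#' neighbours under the distance rule of [select_coupled_neighbors()]. The
#' bias sets the unstimulated firing rate.
#'
#' @param mosaic an `rgc_mosaic`.
#' @param geom an [encoder_geometry()] covering the mosaic field.
#' @param basis_set a [default_basis_set()]-style list (kernels are drawn in
#'   the span of these bases so that model fitting is well-posed).
#' @param seed integer seed.
#' @param target_rate_hz unstimulated firing rate (default 20 Hz).
#' @param stimulus_gain_sd target sd of the stimulus drive to flashed 1/F
#'   textures (log-odds units, default 2).
#' @param coupling_strength peak amplitude of homotypic coupling kernels.
#' @return object of class `rgc_encoder`.
#' @export
sample_ground_truth_params <- function(mosaic, geom,
                                       basis_set = default_basis_set(),
                                       seed = 1,
                                       target_rate_hz = 20,
                                       stimulus_gain_sd = 2,
                                       coupling_strength = 0.6) {
  set.seed(as.integer(seed))
  n <- nrow(mosaic)
  # calibration textures: fixed internal batch for setting stimulus gain
  calib <- lapply(1:30, function(i) {
    generate_texture_image(10000 + i, geom$height, geom$width, 2,
                           geom$pixel_pitch_um)
  })
  bias <- stats::qlogis(target_rate_hz / 1000)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    ty <- mosaic$cell_type[i]
    polarity <- if (grepl("^ON", ty)) 1 else -1
    is_midget <- grepl("midget", ty)
    center_px <- c(um_to_px(mosaic$y_um[i], geom), um_to_px(mosaic$x_um[i], geom))
    radius_px <- mosaic$radius_um[i] / geom$pixel_pitch_um
    crop <- rf_crop(center_px, radius_px, geom)
    w <- dog_filter(crop, center_px, radius_px / 2)
    w <- polarity * w / sqrt(sum(w^2))
    # scale so flashed textures produce drive sd ~ stimulus_gain_sd
    proj_sd <- sd(vapply(calib, function(img) {
      sum(w * (unclass(img)[crop$rows, crop$cols] - BACKGROUND_GRAY))
    }, 0))
    w <- w * stimulus_gain_sd / max(proj_sd, 1e-12)

    tau <- (if (is_midget) 18 else 13) * runif(1, 0.9, 1.1)
    temporal_w <- project_on_basis(basis_set$temporal,
                                   biphasic_kernel(nrow(basis_set$temporal), tau))
    temporal <- as.numeric(basis_set$temporal %*% temporal_w)
    # normalize peak onset step response to 1 (scale lives in the spatial factor)
    peak <- max(abs(cumsum(temporal)))
    temporal <- temporal / peak
    temporal_w <- temporal_w / peak

    fb_shape <- -6 * exp(-(seq_len(nrow(basis_set$feedback))) / 3) -
      0.8 * exp(-(seq_len(nrow(basis_set$feedback))) / 25)
    feedback_w <- project_on_basis(basis_set$feedback, fb_shape)

    nbr <- select_coupled_neighbors(mosaic, mosaic$cell_id[i])
    coupling_w <- NULL
    if (length(nbr) > 0) {
      lagc <- seq_len(nrow(basis_set$coupling))
      # amplitude scaled by 1/sqrt(#neighbours) to keep the network loop gain
      # below 1 (stable collective rates)
      coupling_w <- sapply(nbr, function(j) {
        homo <- mosaic$cell_type[match(j, mosaic$cell_id)] == ty
        amp <- coupling_strength * (if (homo) 1 else 0.25) *
          runif(1, 0.7, 1.3) / sqrt(length(nbr))
        project_on_basis(basis_set$coupling, amp * exp(-lagc / 8))
      })
      coupling_w <- matrix(coupling_w, ncol = length(nbr),
                           dimnames = list(NULL, nbr))
    }
    cells[[i]] <- lnbrc_cell(
      cell_id = mosaic$cell_id[i], cell_type = ty,
      crop_rows = crop$rows, crop_cols = crop$cols, spatial = w,
      temporal_weights = temporal_w, feedback_weights = feedback_w,
      coupling_weights = coupling_w, neighbors = nbr, bias = bias,
      basis_set = basis_set)
  }
  structure(list(cells = cells, mosaic = mosaic, geometry = geom,
                 basis_set = basis_set),
            class = "rgc_encoder")
}

#' Single-cell LNBRC parameters
#'
#' @param cell_id,cell_type identity of the cell.
#' @param crop_rows,crop_cols image rows/cols of the spatial crop.
#' @param spatial spatial filter matrix over the crop (contrast units).
#' @param temporal_weights coefficients on the stimulus-temporal cosine basis.
#' @param feedback_weights coefficients on the feedback cosine basis.
#' @param coupling_weights matrix (coupling basis x neighbours) or NULL.
#' @param neighbors integer `cell_id`s coupled to this cell.
#' @param bias additive constant (log-odds per 1 ms bin).
#' @param basis_set the basis set the weights refer to.
#' @return list of class `lnbrc_cell`; kernels at 1 ms resolution are stored
#'   in `$temporal`, `$feedback`, `$coupling` (list per neighbour).
#' @export
lnbrc_cell <- function(cell_id, cell_type, crop_rows, crop_cols, spatial,
                       temporal_weights, feedback_weights,
                       coupling_weights = NULL, neighbors = integer(0),
                       bias = stats::qlogis(0.02),
                       basis_set = default_basis_set()) {
  temporal <- as.numeric(basis_set$temporal %*% temporal_weights)
  feedback <- as.numeric(basis_set$feedback %*% feedback_weights)
  coupling <- list()
  if (!is.null(coupling_weights) && length(neighbors) > 0) {
    coupling <- lapply(seq_along(neighbors), function(k) {
      as.numeric(basis_set$coupling %*% coupling_weights[, k])
    })
    names(coupling) <- as.character(neighbors)
  }
  structure(list(cell_id = cell_id, cell_type = cell_type,
                 crop_rows = crop_rows, crop_cols = crop_cols,
                 spatial = spatial,
                 temporal_weights = temporal_weights, temporal = temporal,
                 feedback_weights = feedback_weights, feedback = feedback,
                 coupling_weights = coupling_weights, coupling = coupling,
                 neighbors = neighbors, bias = bias),
            class = "lnbrc_cell")
}

#' @export
print.rgc_encoder <- function(x, ...) {
  cat(sprintf("<rgc_encoder> %d cells, image %d x %d px @ %.3g um/px\n",
              length(x$cells), x$geometry$height, x$geometry$width,
              x$geometry$pixel_pitch_um))
  invisible(x)
}

# least-squares projection of a kernel shape onto a basis
project_on_basis <- function(B, shape) {
  as.numeric(qr.solve(crossprod(B), crossprod(B, shape[seq_len(nrow(B))])))
}

# canonical biphasic temporal kernel shape (positive lobe then rebound)
biphasic_kernel <- function(L, tau) {
  t <- seq_len(L)
  (t / tau)^3 * exp(-t / tau) - 0.75 * (t / (1.8 * tau))^3 * exp(-t / (1.8 * tau))
}

dog_filter <- function(crop, center_px, sigma_px) {
  yy <- outer(crop$rows - center_px[1], rep(1, length(crop$cols)))
  xx <- outer(rep(1, length(crop$rows)), crop$cols - center_px[2])
  r2 <- yy^2 + xx^2
  center <- exp(-r2 / (2 * sigma_px^2))
  surround <- exp(-r2 / (2 * (2 * sigma_px)^2))
  center - 0.5 * surround / 4  # surround volume = 0.5 x center volume
}

#' Binned spike trains (cells x 1 ms bins)
#'
#' @param binned integer/numeric matrix with values in `{0, 1}`.
#' @param cell_ids integer ids, one per row.
#' @return matrix of class `spike_trains` with attributes `bin_ms` (always 1)
#'   and `cell_ids`.
#' @export
spike_trains <- function(binned, cell_ids = seq_len(nrow(binned))) {
  if (!all(binned %in% c(0, 1))) stop_invalid("spike trains must be binary")
  structure(binned, bin_ms = 1, cell_ids = cell_ids,
            class = c("spike_trains", "matrix", "array"))
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("<spike_trains> %d cells x %d ms, mean rate %.1f Hz\n",
              nrow(x), ncol(x), 1000 * mean(x)))
  invisible(x)
}

#' Convert spike trains to / from a sparse event table
#' @param spikes a `spike_trains` matrix.
#' @return data.frame with columns `cell_id`, `time_ms`.
#' @export
spikes_to_events <- function(spikes) {
  idx <- which(spikes == 1, arr.ind = TRUE)
  data.frame(cell_id = attr(spikes, "cell_ids")[idx[, 1]],
             time_ms = idx[, 2])[order(idx[, 2]), ]
}

#' @param events data.frame with `cell_id`, `time_ms`.
#' @param cell_ids full roster of cells (rows of the output).
#' @param n_bins total duration in ms.
#' @rdname spikes_to_events
#' @export
events_to_spikes <- function(events, cell_ids, n_bins) {
  m <- matrix(0L, length(cell_ids), n_bins)
  r <- match(events$cell_id, cell_ids)
  m[cbind(r, events$time_ms)] <- 1L
  spike_trains(m, cell_ids)
}
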