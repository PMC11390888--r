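## Evaluation procedures: valid-region masking, shift-searched masked MS-SSIM,
## PSTHs, shift-predictor-corrected cross-correlograms, spike-time
## perturbation, repeat shuffling, and drift / eye-position error metrics.

#' Valid-region mask: convex hull of the receptive fields
#'
#' Only image regions covered by recorded cells are scored; the mask is the
#' filled convex hull of the union of RF disks (center +/- radius),
#' rasterized onto the image grid.
#'
#' @param mosaic an `rgc_mosaic` (>= 3 non-collinear cells).
#' @param geom an [encoder_geometry()].
#' @return logical matrix (height x width) of class `valid_region_mask`.
#' @export
valid_region <- function(mosaic, geom) {
  if (nrow(mosaic) < 3) stop_invalid("need >= 3 cells for a valid region")
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  py <- um_to_px(rep(mosaic$y_um, each = length(ang)) +
                   rep(mosaic$radius_um, each = length(ang)) * sin(ang), geom)
  px <- um_to_px(rep(mosaic$x_um, each = length(ang)) +
                   rep(mosaic$radius_um, each = length(ang)) * cos(ang), geom)
  hull <- chull(px, py)
  if (length(hull) < 3) stop_invalid("degenerate (collinear) receptive-field hull")
  hx <- px[hull]; hy <- py[hull]   # chull returns clockwise order
  gy <- matrix(seq_len(geom$height), geom$height, geom$width)
  gx <- matrix(rep(seq_len(geom$width), each = geom$height), geom$height)
  inside <- matrix(TRUE, geom$height, geom$width)
  n <- length(hull)
  for (e in seq_len(n)) {
    x1 <- hx[e]; y1 <- hy[e]
    x2 <- hx[e %% n + 1]; y2 <- hy[e %% n + 1]
    # clockwise polygon: interior is to the right of each edge
    cross <- (x2 - x1) * (gy - y1) - (y2 - y1) * (gx - x1)
    inside <- inside & (cross <= 1e-9)
  }
  structure(inside, class = c("valid_region_mask", "matrix", "array"))
}

gaussian_kernel_1d <- function(sigma, radius = ceiling(4 * sigma)) {
  k <- dnorm(seq(-radius, radius), sd = sigma)
  k / sum(k)
}

# separable 'same' filtering with reduced-support normalization at edges
filter2_sep <- function(img, k) {
  conv1 <- function(m, k) {
    r <- (length(k) - 1) / 2
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    norm <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - 1 - r
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
      norm[ok] <- norm[ok] + k[j]
    }
    out / norm
  }
  t(conv1(t(conv1(img, k)), k))
}

ssim_maps <- function(x, y, sigma = 1.5, C1 = 0.01^2, C2 = 0.03^2) {
  k <- gaussian_kernel_1d(sigma, radius = 5)
  mx <- filter2_sep(x, k); my <- filter2_sep(y, k)
  sxx <- filter2_sep(x * x, k) - mx^2
  syy <- filter2_sep(y * y, k) - my^2
  sxy <- filter2_sep(x * y, k) - mx * my
  l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
  cs <- (2 * sxy + C2) / (sxx + syy + C2)
  list(ssim = l * cs, cs = cs)
}

downsample2 <- function(m) {
  h <- floor(nrow(m) / 2); w <- floor(ncol(m) / 2)
  0.25 * (m[2 * seq_len(h) - 1, 2 * seq_len(w) - 1, drop = FALSE] +
            m[2 * seq_len(h), 2 * seq_len(w) - 1, drop = FALSE] +
            m[2 * seq_len(h) - 1, 2 * seq_len(w), drop = FALSE] +
            m[2 * seq_len(h), 2 * seq_len(w), drop = FALSE])
}

MS_SSIM_WEIGHTS <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)

ms_ssim_once <- function(x, y, mask) {
  n_scales <- max(1, min(5, floor(log2(min(dim(x)) / 11)) + 1))
  w <- MS_SSIM_WEIGHTS[seq_len(n_scales)]
  w <- w / sum(w)
  val <- 1
  for (s in seq_len(n_scales)) {
    maps <- ssim_maps(x, y)
    m <- if (s == n_scales) maps$ssim else maps$cs
    avg <- mean(m[mask])
    val <- val * max(avg, 1e-6)^w[s]
    if (s < n_scales) {
      x <- downsample2(x); y <- downsample2(y)
      mask <- downsample2(mask + 0) >= 0.5
    }
  }
  val
}

#' Masked, shift-searched multi-scale SSIM
#'
#' MS-SSIM computed only over the valid-region mask, maximized over integer
#' pixel shifts of the reconstruction in `[-max_shift, max_shift]^2` (the
#' absolute position of jointly estimated reconstructions is a gauge
#' freedom). The scale count is reduced automatically for small images
#' (canonical 5-scale weights truncated and renormalized).
#'
#' @param recon,truth image matrices of equal size, values in `[0, 1]`-ish.
#' @param mask logical matrix (default: all pixels).
#' @param max_shift_px shift search radius (default 0).
#' @return list with `score` in `[0, 1]` and `shift`, the `(dy, dx)` offset
#'   applied to `recon` (see [shift_image()]) that maximizes the score.
#' @export
ms_ssim_masked <- function(recon, truth, mask = NULL, max_shift_px = 0) {
  if (!all(dim(recon) == dim(truth))) stop_invalid("images differ in size")
  if (max_shift_px < 0) stop_invalid("'max_shift_px' must be >= 0")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(truth), ncol(truth))
  if (sum(mask) < 121) {
    stop_invalid("mask (%d px) smaller than the minimum SSIM window", sum(mask))
  }
  best <- -Inf; best_shift <- c(0L, 0L)
  truth <- unclass(truth)
  for (dy in -max_shift_px:max_shift_px) {
    for (dx in -max_shift_px:max_shift_px) {
      r <- if (dy == 0 && dx == 0) unclass(recon) else
        shift_image(unclass(recon), c(dy, dx), background = mean(recon))
      sc <- ms_ssim_once(r, truth, mask)
      if (sc > best) { best <- sc; best_shift <- c(dy, dx) }
    }
  }
  list(score = min(max(best, 0), 1), shift = best_shift)
}

#' Peri-stimulus time histogram
#'
#' Spikes in 1 ms bins are smoothed per repeat with a Gaussian kernel
#' (default sd 2 ms) and averaged over repeats.
#'
#' @param repeat_spikes list of `spike_trains` (same cells and duration).
#' @param kernel_sd_ms Gaussian smoothing sd in ms.
#' @return matrix cells x bins of mean smoothed rate (spikes per 1 ms bin).
#' @export
psth <- function(repeat_spikes, kernel_sd_ms = 2) {
  if (length(repeat_spikes) < 1) stop_invalid("need >= 1 repeat")
  k <- gaussian_kernel_1d(kernel_sd_ms)
  r <- (length(k) - 1) / 2
  smooth_one <- function(m) {
    T <- ncol(m)
    padded <- cbind(matrix(0, nrow(m), r), m, matrix(0, nrow(m), r))
    out <- matrix(0, nrow(m), T)
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[, (j - 1) + seq_len(T), drop = FALSE]
    }
    out
  }
  Reduce(`+`, lapply(repeat_spikes, smooth_one)) / length(repeat_spikes)
}

#' Shift-predictor-corrected cross-correlogram
#'
#' Histogram of spike-time differences `t_b - t_a` at 1 ms lags, averaged
#' over repeats. With `shift_correct`, the predictor pairing cell b's
#' response from the *next* repeat (responses to different realizations of
#' the stimulus sequence) is subtracted, removing the component predictable
#' from trial structure alone.
#'
#' @param repeat_spikes list of `spike_trains` repeats.
#' @param cell_a,cell_b row indices of the two cells.
#' @param max_lag_ms maximum lag (must not exceed the trial length).
#' @param shift_correct subtract the shift predictor (needs >= 2 repeats).
#' @return numeric vector of length `2 * max_lag_ms + 1`, names are lags.
#' @export
cross_correlogram <- function(repeat_spikes, cell_a, cell_b, max_lag_ms,
                              shift_correct = TRUE) {
  T <- ncol(repeat_spikes[[1]])
  if (max_lag_ms >= T) stop_invalid("max_lag (%d) exceeds trial length (%d)",
                                    max_lag_ms, T)
  R <- length(repeat_spikes)
  if (shift_correct && R < 2) stop_invalid("shift predictor needs >= 2 repeats")
  lags <- -max_lag_ms:max_lag_ms
  xc_pair <- function(a, b) {
    ta <- which(a == 1); tb <- which(b == 1)
    if (!length(ta) || !length(tb)) return(numeric(length(lags)))
    d <- as.numeric(outer(tb, ta, `-`))
    d <- d[abs(d) <= max_lag_ms]
    tabulate(d + max_lag_ms + 1, nbins = length(lags))
  }
  raw <- Reduce(`+`, lapply(seq_len(R), function(r) {
    xc_pair(repeat_spikes[[r]][cell_a, ], repeat_spikes[[r]][cell_b, ])
  })) / R
  out <- raw
  if (shift_correct) {
    pred <- Reduce(`+`, lapply(seq_len(R), function(r) {
      xc_pair(repeat_spikes[[r]][cell_a, ],
              repeat_spikes[[r %% R + 1]][cell_b, ])
    })) / R
    out <- raw - pred
  }
  names(out) <- lags
  out
}

#' Randomly perturb spike times
#'
#' Each spike is shifted independently by a zero-mean Gaussian interval
#' (re-binned at 1 ms); spikes displaced outside the trial are clipped to the
#' trial bounds, and collisions within one bin collapse to a single spike
#' (binary trains). The number of collapsed spikes is recorded in the
#' `"n_collapsed"` attribute.
#'
#' @param spikes `spike_trains`.
#' @param sigma_ms Gaussian sd in ms (>= 0); 0 returns the input unchanged.
#' @param seed integer seed.
#' @return perturbed `spike_trains`.
#' @export
perturb_spike_times <- function(spikes, sigma_ms, seed = NULL) {
  check_scalar(sigma_ms, "sigma_ms", lower = 0)
  if (sigma_ms == 0) return(spikes)
  if (!is.null(seed)) set.seed(as.integer(seed))
  T <- ncol(spikes)
  out <- matrix(0L, nrow(spikes), T)
  n_collapsed <- 0L
  for (i in seq_len(nrow(spikes))) {
    tt <- which(spikes[i, ] == 1)
    if (!length(tt)) next
    tnew <- round(tt + rnorm(length(tt), sd = sigma_ms))
    tnew <- pmin(pmax(tnew, 1), T)
    n_collapsed <- n_collapsed + length(tnew) - length(unique(tnew))
    out[i, unique(tnew)] <- 1L
  }
  res <- spike_trains(out, attr(spikes, "cell_ids"))
  attr(res, "n_collapsed") <- n_collapsed
  res
}

#' Shuffle repeats independently per cell
#'
#' Reorders the repeated trials of each cell by an independent random
#' permutation: per-cell marginal statistics (PSTH, spike counts) are
#' preserved exactly while cross-cell same-trial pairing (noise correlation)
#' is destroyed.
#'
#' @param repeat_spikes list of `spike_trains` (>= 2 repeats).
#' @param seed integer seed.
#' @return list of `spike_trains`, same shape.
#' @export
shuffle_repeats <- function(repeat_spikes, seed = NULL) {
  R <- length(repeat_spikes)
  if (R < 2) stop_invalid("need >= 2 repeats to shuffle")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_cells <- nrow(repeat_spikes[[1]])
  perms <- lapply(seq_len(n_cells), function(i) sample(R))
  lapply(seq_len(R), function(r) {
    m <- repeat_spikes[[1]]
    for (i in seq_len(n_cells)) {
      m[i, ] <- repeat_spikes[[perms[[i]][r]]][i, ]
    }
    spike_trains(matrix(as.integer(m), nrow(m), ncol(m)),
                 attr(repeat_spikes[[1]], "cell_ids"))
  })
}

#' Realized drift magnitude of a trajectory
#'
#' The standard deviation of the eye position over the trial, pooled over
#' axes as `sqrt(var_x + var_y)` (in um).
#'
#' @param trajectory an `eye_trajectory`, or a frames x 2 matrix of um
#'   positions.
#' @param pool `"pooled"` (default, `sqrt(var_x + var_y)`) or `"mean_axis"`
#'   (mean of the per-axis sds).
#' @return scalar um.
#' @export
realized_drift_magnitude <- function(trajectory, pool = c("pooled", "mean_axis")) {
  pool <- match.arg(pool)
  um <- if (inherits(trajectory, "eye_trajectory")) {
    trajectory$displacements_um
  } else trajectory
  if (nrow(um) < 2) return(0)
  v <- apply(um, 2, var)
  switch(pool, pooled = sqrt(sum(v)), mean_axis = mean(sqrt(v)))
}

#' Eye-position estimation error
#'
#' Per-frame Euclidean distance between the true and estimated eye paths
#' after removing the global translation gauge (joint estimation only
#' determines position relative to the reconstructed image), by subtracting
#' each path's mean.
#'
#' @param true_trajectory `eye_trajectory` or frames x 2 um matrix.
#' @param estimated frames x 2 um matrix (e.g. the posterior-mean path).
#' @param align `"mean"` (default) removes each path's mean; `"none"` keeps
#'   absolute positions.
#' @return list with `per_frame` (um) and `mean` (scalar um).
#' @export
eye_position_error <- function(true_trajectory, estimated,
                               align = c("mean", "none")) {
  align <- match.arg(align)
  tr <- if (inherits(true_trajectory, "eye_trajectory")) {
    true_trajectory$displacements_um
  } else true_trajectory
  if (nrow(tr) != nrow(estimated)) {
    stop_invalid("trajectory lengths differ (%d vs %d)",
                 nrow(tr), nrow(estimated))
  }
  if (align == "mean") {
    tr <- sweep(tr, 2, colMeans(tr))
    estimated <- sweep(estimated, 2, colMeans(estimated))
  }
  d <- sqrt(rowSums((tr - estimated)^2))
  list(per_frame = d, mean = mean(d))
}
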