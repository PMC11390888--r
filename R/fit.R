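## Maximum-likelihood fitting of LNBRC / LNBR / LNP encoders.
##
## The rank-1 stimulus filter makes each side of the problem convex:
## coordinate descent alternates between (spatial, feedback, coupling, bias)
## with the temporal kernel fixed, and (temporal, feedback, coupling, bias)
## with the spatial map fixed. Each side is solved with FISTA (accelerated
## proximal gradient, backtracking line search, restart on increase) with an
## L1 penalty on the spatial spline coefficients and a group-L2,1 penalty on
## the coupling basis weights.

#' Fitting configuration
#'
#' @param l1_weight L1 penalty on the spatial spline coefficients (>= 0).
#' @param group_l21_weight group-sparsity penalty on coupling weights (>= 0).
#' @param max_iter FISTA iteration cap per side (a vector is recycled over
#'   the alternation sides, e.g. `c(80, 50, 40, 30)`).
#' @param tol relative objective-change stopping tolerance.
#' @param rounds alternation rounds (default 2).
#' @return list of class `fit_config`.
#' @export
fit_config <- function(l1_weight = 1e-4, group_l21_weight = 1e-3,
                       max_iter = 500, tol = 1e-9, rounds = 2) {
  if (l1_weight < 0 || group_l21_weight < 0) {
    stop_invalid("regularization weights must be >= 0")
  }
  structure(list(l1_weight = l1_weight, group_l21_weight = group_l21_weight,
                 max_iter = max_iter, tol = tol, rounds = rounds),
            class = "fit_config")
}

# per-frame projections of the stimulus crop onto the spatial basis columns
frame_projection_matrix <- function(stimulus, crop, B) {
  nb <- ncol(B)
  if (inherits(stimulus, "flashed_stimulus_set")) {
    n_img <- length(stimulus$images)
    Pimg <- matrix(0, n_img, nb)
    for (k in seq_len(n_img)) {
      v <- as.numeric(unclass(stimulus$images[[k]])[crop$rows, crop$cols]) -
        BACKGROUND_GRAY
      Pimg[k, ] <- as.numeric(v %*% B)
    }
    fpt <- stimulus$n_frames_per_trial
    Pf <- matrix(0, n_img * fpt, nb)
    for (k in seq_len(n_img)) {
      Pf[(k - 1) * fpt + stimulus$flash_frames, ] <-
        matrix(Pimg[k, ], length(stimulus$flash_frames), nb, byrow = TRUE)
    }
    Pf
  } else if (inherits(stimulus, "drift_stimulus_set")) {
    fpt <- stimulus$n_frames_per_trial
    n_tr <- length(stimulus$images)
    Pf <- matrix(0, n_tr * fpt, nb)
    for (k in seq_len(n_tr)) {
      img <- unclass(stimulus$images[[k]])
      px <- stimulus$trajectories[[k]]$displacements_px
      for (f in seq_len(fpt)) {
        v <- as.numeric(shift_image(img, px[f, ])[crop$rows, crop$cols]) -
          BACKGROUND_GRAY
        Pf[(k - 1) * fpt + f, ] <- as.numeric(v %*% B)
      }
    }
    Pf
  } else if (inherits(stimulus, "stim_movie")) {
    nF <- dim(stimulus$frames)[3]
    Pf <- matrix(0, nF, nb)
    for (f in seq_len(nF)) {
      v <- as.numeric(stimulus$frames[crop$rows, crop$cols, f]) - BACKGROUND_GRAY
      Pf[f, ] <- as.numeric(v %*% B)
    }
    Pf
  } else stop_invalid("unsupported stimulus class")
}

# causal convolution of every (frame-indexed) column of Pf with kernel k,
# two columns per FFT; `fob` maps 1 ms bins to frames
conv_causal_cols <- function(Pf, k, fob) {
  T <- length(fob); L <- length(k)
  n <- stats::nextn(T + L + 1, c(2, 3, 5))
  kf <- fft(c(0, k, numeric(n - L - 1)))
  out <- matrix(0, T, ncol(Pf))
  j <- 1
  while (j <= ncol(Pf)) {
    if (j + 1 <= ncol(Pf)) {
      z <- complex(real = c(Pf[fob, j], numeric(n - T)),
                   imaginary = c(Pf[fob, j + 1], numeric(n - T)))
      y <- fft(fft(z) * kf, inverse = TRUE) / n
      out[, j] <- Re(y)[seq_len(T)]
      out[, j + 1] <- Im(y)[seq_len(T)]
      j <- j + 2
    } else {
      out[, j] <- conv_causal(Pf[fob, j], k)
      j <- j + 1
    }
  }
  out
}

# design blocks shared by both sides: feedback / coupling / bias
history_design <- function(spikes, cell_row, nbr_rows, basis_set, T) {
  own_idx <- which(spikes[cell_row, ] == 1)
  Xf <- spike_basis_conv(own_idx, unclass(basis_set$feedback), T)
  Xc <- NULL
  if (length(nbr_rows) > 0) {
    Xc <- do.call(cbind, lapply(nbr_rows, function(r) {
      spike_basis_conv(which(spikes[r, ] == 1), unclass(basis_set$coupling), T)
    }))
  }
  list(Xf = Xf, Xc = Xc)
}

# unit-RMS column scaling for the optimizer (diagonal preconditioning);
# grouped (coupling) columns share one scale so the group-L2,1 penalty keeps
# its meaning, and penalty weights are rescaled to preserve the objective
column_scales <- function(blocks, grp) {
  sc <- unlist(lapply(blocks, function(b) {
    if (is.null(b)) 1 else as.numeric(cpp_col_rms(b))
  }))
  for (g in unique(grp[grp > 0])) {
    idx <- which(grp == g)
    sc[idx] <- max(mean(sc[idx]), 1e-8)
  }
  pmax(sc, 1e-8)
}

fit_lnbrc_cell <- function(stimulus, spikes, mosaic, geom, cell_id,
                           basis_set, config, coupled = TRUE) {
  ids_sp <- attr(spikes, "cell_ids")
  i_m <- match(cell_id, mosaic$cell_id)
  cell_row <- match(cell_id, ids_sp)
  T <- ncol(spikes)
  center_px <- c(um_to_px(mosaic$y_um[i_m], geom), um_to_px(mosaic$x_um[i_m], geom))
  radius_px <- mosaic$radius_um[i_m] / geom$pixel_pitch_um
  # tighter crop than the simulator default: the spline grid must resolve
  # the DoG center lobe, so trade outer-surround coverage for knot density
  crop <- rf_crop(center_px, radius_px, geom, crop_factor = 1.8)
  sb <- spline_spatial_basis(crop$rows, crop$cols, basis_set$spatial_n)
  Pf <- frame_projection_matrix(stimulus, crop, sb$B)
  fp <- stimulus$frame_period_ms
  fob <- frame_of_bin(T, fp)

  nbr <- if (coupled) select_coupled_neighbors(mosaic, cell_id) else integer(0)
  nbr <- nbr[nbr %in% ids_sp]
  hd <- history_design(spikes, cell_row, match(nbr, ids_sp), basis_set, T)
  s <- as.numeric(spikes[cell_row, ])

  nb_sp <- ncol(sb$B)
  nb_t <- ncol(basis_set$temporal)
  nb_f <- ncol(basis_set$feedback)
  nb_c <- ncol(basis_set$coupling)
  n_nbr <- length(nbr)

  # initial values
  sw <- numeric(nb_sp)
  tw <- project_on_basis(basis_set$temporal,
                         biphasic_kernel(nrow(basis_set$temporal), 15))
  tw <- tw / max(abs(cumsum(as.numeric(basis_set$temporal %*% tw))))
  fw <- numeric(nb_f)
  cw <- if (n_nbr > 0) matrix(0, nb_c, n_nbr) else NULL
  bias <- stats::qlogis(max(mean(s), 1e-5))

  side_objective <- numeric(0)
  iters <- integer(0)
  pen_total <- function(sw, cw) {
    config$l1_weight * sum(abs(sw)) +
      (if (n_nbr > 0) config$group_l21_weight *
         sum(apply(cw, 2, function(v) sqrt(sum(v^2)))) else 0)
  }
  for (round in seq_len(config$rounds)) {
    ## side A: spatial + history + bias (temporal fixed)
    kern <- as.numeric(basis_set$temporal %*% tw)
    Xs <- conv_causal_cols(Pf, kern, fob)
    blocks <- c(list(Xs, hd$Xf), if (n_nbr > 0) list(hd$Xc),
                list(NULL))   # trailing NULL = intercept column
    p_tot <- nb_sp + nb_f + nb_c * n_nbr + 1
    l1w <- c(rep(config$l1_weight, nb_sp), numeric(p_tot - nb_sp))
    grp <- integer(p_tot)
    if (n_nbr > 0) {
      grp[nb_sp + nb_f + seq_len(nb_c * n_nbr)] <-
        rep(seq_len(n_nbr), each = nb_c)
    }
    theta0 <- c(sw, fw, if (n_nbr > 0) as.numeric(cw), bias)
    side_iters <- rep(config$max_iter, length.out = 2 * config$rounds)
    sc <- column_scales(blocks, grp)
    fit <- cpp_fista_glm(blocks, numeric(T), s, "bernoulli",
                         l1w / sc, grp, config$group_l21_weight, theta0 * sc,
                         side_iters[2 * round - 1], config$tol, sc)
    rm(Xs, blocks)
    if (isTRUE(fit$diverged)) {
      stop(sprintf("FISTA diverged on spatial side (step size %.3g)",
                   fit$step_size), call. = FALSE)
    }
    th <- fit$theta / sc
    sw <- th[seq_len(nb_sp)]
    fw <- th[nb_sp + seq_len(nb_f)]
    if (n_nbr > 0) cw <- matrix(th[nb_sp + nb_f + seq_len(nb_c * n_nbr)], nb_c)
    bias <- th[length(th)]
    nll <- tail(fit$objective, 1) -
      (config$l1_weight * sum(abs(sw)) +
         (if (n_nbr > 0) config$group_l21_weight *
            sum(apply(cw, 2, function(v) sqrt(sum(v^2)))) else 0))
    side_objective <- c(side_objective, nll + pen_total(sw, cw))
    iters <- c(iters, fit$iterations)

    ## side B: temporal + history + bias (spatial fixed)
    zf <- as.numeric(Pf %*% sw)
    Xt <- matrix(0, T, nb_t)
    z <- zf[fob]
    for (cidx in seq_len(nb_t)) {
      Xt[, cidx] <- conv_causal(z, unclass(basis_set$temporal)[, cidx])
    }
    blocks <- c(list(Xt, hd$Xf), if (n_nbr > 0) list(hd$Xc), list(NULL))
    p_tot <- nb_t + nb_f + nb_c * n_nbr + 1
    l1w <- numeric(p_tot)
    grp <- integer(p_tot)
    if (n_nbr > 0) {
      grp[nb_t + nb_f + seq_len(nb_c * n_nbr)] <-
        rep(seq_len(n_nbr), each = nb_c)
    }
    theta0 <- c(tw, fw, if (n_nbr > 0) as.numeric(cw), bias)
    sc <- column_scales(blocks, grp)
    fit <- cpp_fista_glm(blocks, numeric(T), s, "bernoulli",
                         l1w / sc, grp, config$group_l21_weight, theta0 * sc,
                         side_iters[2 * round], config$tol, sc)
    rm(Xt, blocks)
    if (isTRUE(fit$diverged)) {
      stop(sprintf("FISTA diverged on temporal side (step size %.3g)",
                   fit$step_size), call. = FALSE)
    }
    th <- fit$theta / sc
    tw <- th[seq_len(nb_t)]
    fw <- th[nb_t + seq_len(nb_f)]
    if (n_nbr > 0) cw <- matrix(th[nb_t + nb_f + seq_len(nb_c * n_nbr)], nb_c)
    bias <- th[length(th)]
    nll <- tail(fit$objective, 1) -
      (if (n_nbr > 0) config$group_l21_weight *
         sum(apply(cw, 2, function(v) sqrt(sum(v^2)))) else 0)
    side_objective <- c(side_objective, nll + pen_total(sw, cw))
    iters <- c(iters, fit$iterations)

    ## gauge: unit-L2 spatial map, scale absorbed into the temporal factor
    smap <- sb$B %*% sw
    nrm <- sqrt(sum(smap^2))
    if (nrm > 1e-10) {
      sw <- sw / nrm
      tw <- tw * nrm
    }
  }
  spatial <- matrix(sb$B %*% sw, length(crop$rows), length(crop$cols))
  cellfit <- lnbrc_cell(cell_id = cell_id,
                        cell_type = mosaic$cell_type[i_m],
                        crop_rows = crop$rows, crop_cols = crop$cols,
                        spatial = spatial,
                        temporal_weights = tw, feedback_weights = fw,
                        coupling_weights = cw, neighbors = nbr,
                        bias = bias, basis_set = basis_set)
  cellfit$spatial_weights <- sw
  list(cell = cellfit,
       report = list(objective = side_objective, iterations = iters))
}

fit_lnp_cell <- function(stimulus, spikes, mosaic, geom, cell_id,
                         basis_set, config) {
  i_m <- match(cell_id, mosaic$cell_id)
  cell_row <- match(cell_id, attr(spikes, "cell_ids"))
  center_px <- c(um_to_px(mosaic$y_um[i_m], geom), um_to_px(mosaic$x_um[i_m], geom))
  radius_px <- mosaic$radius_um[i_m] / geom$pixel_pitch_um
  crop <- rf_crop(center_px, radius_px, geom, crop_factor = 1.8)
  sb <- spline_spatial_basis(crop$rows, crop$cols, basis_set$spatial_n)
  Pf <- frame_projection_matrix(stimulus, crop, sb$B)
  fp <- stimulus$frame_period_ms
  counts <- as.numeric(bin_spikes_per_frame(
    spikes[cell_row, , drop = FALSE], fp))
  Fn <- min(nrow(Pf), length(counts))
  Pf <- Pf[seq_len(Fn), , drop = FALSE]; counts <- counts[seq_len(Fn)]
  # temporal basis over frame lags 0..L-1 (current frame included)
  Bt <- raised_cosine_basis(6, 1, 31, log_stretch = 3)
  nb_sp <- ncol(sb$B); nb_t <- ncol(Bt)
  sw <- numeric(nb_sp)
  tw <- project_on_basis(Bt, exp(-(seq_len(31) - 1) / 3))
  bias <- log(max(mean(counts), 1e-5))
  side_objective <- numeric(0)
  frame_conv <- function(x, k) {   # lag 0 included
    g <- numeric(length(x))
    for (tau in seq_along(k)) {
      idx <- seq_len(length(x) - tau + 1)
      g[idx + tau - 1] <- g[idx + tau - 1] + k[tau] * x[idx]
    }
    g
  }
  for (round in seq_len(config$rounds)) {
    kern <- as.numeric(Bt %*% tw)
    Xs <- apply(Pf, 2, frame_conv, k = kern)
    blocks <- list(Xs, NULL)
    scp <- column_scales(blocks, integer(nb_sp + 1))
    fit <- cpp_fista_glm(blocks, numeric(Fn), counts,
                         "poisson", c(rep(config$l1_weight, nb_sp), 0) / scp,
                         integer(nb_sp + 1), 0, c(sw, bias) * scp,
                         max(config$max_iter), config$tol, scp)
    th <- fit$theta / scp
    sw <- th[seq_len(nb_sp)]; bias <- tail(th, 1)
    side_objective <- c(side_objective, tail(fit$objective, 1))
    z <- as.numeric(Pf %*% sw)
    Xt <- apply(unclass(Bt), 2, function(k) frame_conv(z, k))
    blocks <- list(Xt, NULL)
    scp <- column_scales(blocks, integer(nb_t + 1))
    fit <- cpp_fista_glm(blocks, numeric(Fn), counts,
                         "poisson", numeric(nb_t + 1), integer(nb_t + 1), 0,
                         c(tw, bias) * scp, max(config$max_iter), config$tol,
                         scp)
    th <- fit$theta / scp
    tw <- th[seq_len(nb_t)]; bias <- tail(th, 1)
    side_objective <- c(side_objective,
                        tail(fit$objective, 1) + config$l1_weight * sum(abs(sw)))
  }
  spatial <- matrix(sb$B %*% sw, length(crop$rows), length(crop$cols))
  list(cell = lnp_cell(crop$rows, crop$cols, spatial,
                       as.numeric(Bt %*% tw), bias),
       report = list(objective = side_objective))
}

#' Fit an encoding model to spike trains
#'
#' @param stimulus a `flashed_stimulus_set`, `drift_stimulus_set`, or
#'   `stim_movie`.
#' @param spikes `spike_trains` (1 ms bins) for all cells.
#' @param mosaic the `rgc_mosaic` (RF geometry and coupling rule).
#' @param geom [encoder_geometry()].
#' @param model `"lnbrc"` (coupled), `"lnbr"` (uncoupled) or `"lnp"`.
#' @param basis_set see [default_basis_set()].
#' @param config a [fit_config()].
#' @param cells subset of `cell_id`s to fit (default: all in `spikes`).
#' @param verbose print progress.
#' @return for lnbrc/lnbr: an `rgc_encoder` with `$fit_report` (per-cell
#'   objective traces, nonincreasing across rounds); for lnp: an
#'   `lnp_encoder`.
#' @export
fit_encoder <- function(stimulus, spikes, mosaic, geom,
                        model = c("lnbrc", "lnbr", "lnp"),
                        basis_set = default_basis_set(),
                        config = fit_config(), cells = NULL,
                        verbose = FALSE) {
  model <- match.arg(model)
  ids <- attr(spikes, "cell_ids")
  if (is.null(cells)) cells <- ids
  fits <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    if (verbose) message(sprintf("fitting cell %d/%d", k, length(cells)))
    if (k %% 4 == 0) gc(FALSE)
    fits[[k]] <- switch(model,
      lnbrc = fit_lnbrc_cell(stimulus, spikes, mosaic, geom, cells[k],
                             basis_set, config, coupled = TRUE),
      lnbr = fit_lnbrc_cell(stimulus, spikes, mosaic, geom, cells[k],
                            basis_set, config, coupled = FALSE),
      lnp = fit_lnp_cell(stimulus, spikes, mosaic, geom, cells[k],
                         basis_set, config))
  }
  report <- lapply(fits, `[[`, "report")
  names(report) <- as.character(cells)
  if (model == "lnp") {
    structure(list(cells = lapply(fits, `[[`, "cell"), mosaic = mosaic,
                   geometry = geom, fit_report = report, model = model),
              class = "lnp_encoder")
  } else {
    structure(list(cells = lapply(fits, `[[`, "cell"), mosaic = mosaic,
                   geometry = geom, basis_set = basis_set,
                   fit_report = report, model = model),
              class = "rgc_encoder")
  }
}

#' Subset trials of a stimulus set and the matching spike bins
#' @param stimulus flashed or drift stimulus set.
#' @param spikes `spike_trains` covering all trials.
#' @param trials integer trial indices to keep.
#' @return list with `stimulus` and `spikes` restricted to those trials.
#' @export
subset_trials <- function(stimulus, spikes, trials) {
  fpt <- stimulus$n_frames_per_trial
  fp <- stimulus$frame_period_ms
  bins_per_trial <- bins_for_frames(fpt, fp)
  keep_bins <- as.numeric(vapply(trials, function(k) {
    (k - 1) * bins_per_trial + seq_len(bins_per_trial)
  }, numeric(bins_per_trial)))
  sub <- if (inherits(stimulus, "flashed_stimulus_set")) {
    flashed_stimulus_set(stimulus$images[trials], stimulus$flash_ms,
                         stimulus$gray_ms, fp)
  } else {
    drift_stimulus_set(stimulus$images[trials], stimulus$trajectories[trials],
                       fp)
  }
  list(stimulus = sub,
       spikes = spike_trains(spikes[, keep_bins, drop = FALSE],
                             attr(spikes, "cell_ids")))
}

#' Grid search for regularization hyperparameters
#'
#' Fits a few representative cells of each type on a training subset of
#' trials for every grid point and returns the point minimizing the mean
#' held-out negative log-likelihood. All cells of a given type share the
#' selected hyperparameters.
#'
#' @param stimulus,spikes,mosaic,geom as in [fit_encoder()].
#' @param grid data.frame with columns `l1_weight`, `group_l21_weight`.
#' @param cells_per_type cells sampled per type (default 4).
#' @param heldout_frac fraction of trials held out for evaluation.
#' @param model,basis_set,config,seed see [fit_encoder()].
#' @return list with `best` (row of `grid`), `scores` (mean held-out NLL per
#'   grid point), `cells` used.
#' @export
grid_search_hyperparams <- function(stimulus, spikes, mosaic, geom, grid,
                                    cells_per_type = 4, heldout_frac = 0.2,
                                    model = "lnbrc",
                                    basis_set = default_basis_set(),
                                    config = fit_config(), seed = 1) {
  if (nrow(grid) == 0) stop_invalid("hyperparameter grid is empty")
  set.seed(as.integer(seed))
  ids <- attr(spikes, "cell_ids")
  present <- mosaic[mosaic$cell_id %in% ids, ]
  eval_cells <- unlist(lapply(split(present$cell_id, present$cell_type),
                              function(v) {
    sample(v, min(cells_per_type, length(v)))
  }), use.names = FALSE)
  n_tr <- length(stimulus$images)
  n_test <- max(1, round(heldout_frac * n_tr))
  test_tr <- seq(n_tr - n_test + 1, n_tr)
  train_tr <- setdiff(seq_len(n_tr), test_tr)
  train <- subset_trials(stimulus, spikes, train_tr)
  test <- subset_trials(stimulus, spikes, test_tr)
  scores <- numeric(nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    cfg <- config
    cfg$l1_weight <- grid$l1_weight[gidx]
    cfg$group_l21_weight <- grid$group_l21_weight[gidx]
    enc <- fit_encoder(train$stimulus, train$spikes, mosaic, geom,
                       model = model, basis_set = basis_set, config = cfg,
                       cells = eval_cells)
    scores[gidx] <- mean(vapply(eval_cells, function(cid) {
      lnbrc_nll(enc, test$stimulus, test$spikes, cid,
                include_coupling = (model == "lnbrc"))
    }, 0))
  }
  list(best = grid[which.min(scores), , drop = FALSE], scores = scores,
       cells = eval_cells)
}

#' Fraction of PSTH variance explained by an encoder
#'
#' Compares the PSTH of simulated model repeats against the PSTH of data
#' repeats: `1 - MSE(model, data) / Var(data)` per cell.
#'
#' @param encoder fitted or ground-truth `rgc_encoder`.
#' @param stimulus repeated stimulus.
#' @param repeat_spikes list of `spike_trains`, one per data repeat (>= 2).
#' @param kernel_sd_ms PSTH smoothing kernel sd (default 2 ms).
#' @param n_model_repeats simulated repeats (default 2x data repeats).
#' @param seed RNG seed for the model simulation.
#' @return numeric vector per cell; cells with zero-variance data PSTH are NA.
#' @export
fraction_psth_variance_explained <- function(encoder, stimulus, repeat_spikes,
                                             kernel_sd_ms = 2,
                                             n_model_repeats = 2 * length(repeat_spikes),
                                             seed = 1) {
  if (length(repeat_spikes) < 2) stop_invalid("need >= 2 repeats")
  data_psth <- psth(repeat_spikes, kernel_sd_ms)
  model_rep <- simulate_repeats(encoder, stimulus, n_model_repeats, seed)
  model_psth <- psth(model_rep, kernel_sd_ms)
  vapply(seq_len(nrow(data_psth)), function(i) {
    v <- var(data_psth[i, ])
    if (v <= .Machine$double.eps) return(NA_real_)
    1 - mean((model_psth[i, ] - data_psth[i, ])^2) / v
  }, 0)
}
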