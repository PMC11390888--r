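## End-to-end synthetic experiments: configuration, validation, and the
## simulate -> (fit) -> reconstruct -> evaluate pipeline runner.

#' Default experiment configuration
#'
#' A minimal flashed-image experiment (small image, few cells) that runs in
#' seconds; every stochastic stage carries an explicit seed. Configurations
#' are plain nested lists and round-trip losslessly through JSON.
#'
#' @return nested list of class `experiment_config`.
#' @export
default_experiment_config <- function() {
  structure(list(
    stimulus = list(kind = "flash", height = 32, width = 32,
                    pixel_pitch_um = DEFAULT_PIXEL_PITCH_UM,
                    n_trials = 2, flash_ms = 100, gray_ms = 400,
                    n_frames = 60, diffusion_um2_per_frame = 10,
                    spectral_exponent = 2),
    retina = list(jitter_fraction = 0.1, target_rate_hz = 20,
                  stimulus_gain_sd = 2, coupling_strength = 0.6,
                  midget_spacing_um = 70, parasol_spacing_um = 140),
    fit = list(enabled = FALSE, model = "lnbrc", l1_weight = 1e-4,
               group_l21_weight = 1e-3, rounds = 2, max_iter = 200),
    reconstruction = list(mode = "flash", prior = "one_over_f", lambda = 1,
                          rho_start = 0.1, rho_end = 10, K = 10),
    evaluation = list(max_shift_px = 0),
    seeds = list(stimulus = 1, retina = 2, spikes = 3, reconstruction = 4)),
    class = "experiment_config")
}

#' Validate an experiment configuration
#'
#' Schema and cross-field checks (required keys, positivity, mode/stimulus
#' compatibility).
#'
#' @param config an experiment config list.
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  need <- c("stimulus", "retina", "fit", "reconstruction", "evaluation", "seeds")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    return(sprintf("missing config block: %s", missing))
  }
  st <- config$stimulus
  if (!st$kind %in% c("flash", "drift")) {
    problems <- c(problems, "stimulus.kind must be 'flash' or 'drift'")
  }
  if (isTRUE(st$diffusion_um2_per_frame < 0)) {
    problems <- c(problems, "stimulus.diffusion_um2_per_frame must be >= 0")
  }
  if (st$height < 16 || st$width < 16) {
    problems <- c(problems, "stimulus.height/width must be >= 16")
  }
  rc <- config$reconstruction
  if (!rc$mode %in% c("flash", "known", "zero", "joint", "noiseless")) {
    problems <- c(problems, "reconstruction.mode invalid")
  }
  if (st$kind == "flash" && rc$mode %in% c("known", "joint")) {
    problems <- c(problems,
                  "reconstruction.mode 'known'/'joint' requires stimulus.kind 'drift'")
  }
  if (st$kind == "drift" && rc$mode == "flash") {
    problems <- c(problems,
                  "reconstruction.mode 'flash' requires stimulus.kind 'flash'")
  }
  if (!rc$prior %in% c("one_over_f", "gaussian", "dcnn")) {
    problems <- c(problems, "reconstruction.prior invalid")
  }
  if (rc$rho_start <= 0 || rc$rho_end <= rc$rho_start) {
    problems <- c(problems, "reconstruction rho schedule must be increasing and positive")
  }
  seeds <- config$seeds
  for (k in c("stimulus", "retina", "spikes", "reconstruction")) {
    if (is.null(seeds[[k]])) problems <- c(problems, sprintf("seeds.%s missing", k))
  }
  problems
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(as.character(js))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

build_prior <- function(config, height, width, pitch) {
  rc <- config$reconstruction
  switch(rc$prior,
    one_over_f = one_over_f_prior(1, height, width),
    gaussian = {
      w <- matrix(1, height, width); w[1, 1] <- 0
      w
    },
    dcnn = {
      corpus <- lapply(seq_len(200), function(i) {
        generate_texture_image(5000 + i, height, width,
                               config$stimulus$spectral_exponent, pitch)
      })
      train_stand_in_denoiser(corpus, seed = config$seeds$reconstruction)
    })
}

#' Run a full synthetic experiment
#'
#' Simulates stimuli and spikes, optionally fits an encoder, reconstructs
#' every trial, and evaluates masked MS-SSIM. Writes a config echo (with
#' hash), per-stage log, tidy metrics CSV, and a PNG preview of the first
#' reconstruction into `out_dir`. Identical config and seeds give identical
#' metrics.
#'
#' @param config an experiment config (see [default_experiment_config()]).
#' @param out_dir output directory (created if needed); NULL to skip writing.
#' @return list with `metrics` (data.frame), `encoder`, `results` (list of
#'   `recon_result`), `out_dir`.
#' @export
run_experiment <- function(config = default_experiment_config(),
                           out_dir = NULL) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop(paste(c("invalid config:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  st <- config$stimulus
  log_lines <- sprintf("[%s] config hash %s", format(Sys.time()),
                       config_hash(config))
  geom <- encoder_geometry(st$height, st$width, st$pixel_pitch_um)
  field <- c(st$height, st$width) * st$pixel_pitch_um

  images <- lapply(seq_len(st$n_trials), function(k) {
    generate_texture_image(config$seeds$stimulus + k, st$height, st$width,
                           st$spectral_exponent, st$pixel_pitch_um)
  })
  if (st$kind == "drift") {
    set.seed(config$seeds$stimulus)
    trajectories <- lapply(seq_len(st$n_trials), function(k) {
      simulate_drift_trajectory(st$n_frames, st$diffusion_um2_per_frame,
                                st$pixel_pitch_um)
    })
    stimulus <- drift_stimulus_set(images, trajectories)
  } else {
    stimulus <- flashed_stimulus_set(images, st$flash_ms, st$gray_ms)
  }

  rt <- config$retina
  mosaic <- build_mosaic(field,
                         spacings_um = c(ON_parasol = rt$parasol_spacing_um,
                                         OFF_parasol = rt$parasol_spacing_um,
                                         ON_midget = rt$midget_spacing_um,
                                         OFF_midget = rt$midget_spacing_um),
                         jitter_fraction = rt$jitter_fraction,
                         seed = config$seeds$retina)
  truth <- sample_ground_truth_params(mosaic, geom, seed = config$seeds$retina,
                                      target_rate_hz = rt$target_rate_hz,
                                      stimulus_gain_sd = rt$stimulus_gain_sd,
                                      coupling_strength = rt$coupling_strength)
  spikes <- simulate_spikes(truth, stimulus, mode = "network",
                            seed = config$seeds$spikes)
  log_lines <- c(log_lines, sprintf("simulated %d cells x %d ms",
                                    nrow(spikes), ncol(spikes)))

  encoder <- truth
  if (isTRUE(config$fit$enabled)) {
    cfg <- fit_config(config$fit$l1_weight, config$fit$group_l21_weight,
                      max_iter = config$fit$max_iter,
                      rounds = config$fit$rounds)
    encoder <- fit_encoder(stimulus, spikes, mosaic, geom,
                           model = config$fit$model, config = cfg)
    log_lines <- c(log_lines, sprintf("fitted %s encoder", config$fit$model))
  }

  rc <- config$reconstruction
  prior <- build_prior(config, st$height, st$width, st$pixel_pitch_um)
  schedule <- rho_schedule(rc$rho_start, rc$rho_end, rc$K)
  mask <- valid_region(mosaic, geom)
  timing <- if (st$kind == "flash") {
    trial_timing("flash", stimulus$n_frames_per_trial,
                 flash_frames = stimulus$flash_frames)
  } else {
    trial_timing("drift", st$n_frames)
  }
  bins_per_trial <- bins_for_frames(timing$n_frames, timing$frame_period_ms)
  set.seed(config$seeds$reconstruction)
  results <- vector("list", st$n_trials)
  rows <- list()
  for (k in seq_len(st$n_trials)) {
    cols <- (k - 1) * bins_per_trial + seq_len(bins_per_trial)
    sk <- spike_trains(spikes[, cols, drop = FALSE], attr(spikes, "cell_ids"))
    res <- switch(rc$mode,
      flash = reconstruct_flashed_map(sk, encoder, prior, schedule, rc$lambda,
                                      timing, mask = mask),
      zero = reconstruct_known_em(sk, encoder, prior,
                                  zero_trajectory(timing$n_frames),
                                  schedule, rc$lambda, timing, mask = mask),
      known = reconstruct_known_em(sk, encoder, prior,
                                   stimulus$trajectories[[k]],
                                   schedule, rc$lambda, timing, mask = mask),
      joint = reconstruct_joint_em(sk, encoder, prior, timing,
                                   lambda = rc$lambda,
                                   diffusion_um2_per_frame =
                                     st$diffusion_um2_per_frame, mask = mask),
      noiseless = {
        M <- linear_projection_matrix(encoder)
        sobs <- as.numeric(crossprod(M, as.numeric(unclass(images[[k]]))))
        reconstruct_noiseless_linear(sobs, M, prior, schedule, rc$lambda,
                                     st$height, st$width, mask = mask)
      })
    results[[k]] <- res
    ms <- ms_ssim_masked(res$image, unclass(images[[k]]), mask,
                         config$evaluation$max_shift_px)
    rows[[k]] <- data.frame(trial = k, condition = rc$mode,
                            metric = "ms_ssim", value = ms$score)
  }
  metrics <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_out <- unclass(config)
    cfg_out$hash <- config_hash(config)
    jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    write_image_png(results[[1]]$image, file.path(out_dir, "recon_trial1.png"))
    write_mosaic_csv(mosaic, file.path(out_dir, "mosaic.csv"))
  }
  list(metrics = metrics, encoder = encoder, results = results,
       mosaic = mosaic, out_dir = out_dir)
}
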