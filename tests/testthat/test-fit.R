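# Small-scale fitting checks; full-scale parameter recovery lives in
# test-acceptance.R.

fit_fixture <- function() {
  memo_fixture("fit_fixture", function() {
    set.seed(71)
    geom <- encoder_geometry(32, 32, 11)
    mos <- build_mosaic(c(300, 300), spacings_um = c(ON_midget = 80),
                        jitter_fraction = 0.08, seed = 72)
    enc <- sample_ground_truth_params(mos, geom, seed = 73)
    imgs <- lapply(1:200, function(k) generate_texture_image(6000 + k, 32, 32))
    stim <- flashed_stimulus_set(imgs)
    spikes <- simulate_spikes(enc, stim, mode = "network", seed = 74)
    list(geom = geom, mos = mos, enc = enc, stim = stim, spikes = spikes)
  })
}

filter_cos_sim <- function(fitcell, trucell, geom) {
  w1 <- matrix(0, geom$height, geom$width)
  w1[fitcell$crop_rows, fitcell$crop_cols] <- fitcell$spatial
  w2 <- matrix(0, geom$height, geom$width)
  w2[trucell$crop_rows, trucell$crop_cols] <- trucell$spatial
  sum(w1 * w2) / sqrt(sum(w1^2) * sum(w2^2))
}

test_that("LNBRC fitting recovers filters with monotone objectives", {
  fx <- fit_fixture()
  cells <- fx$mos$cell_id[2:4]
  fit <- fit_encoder(fx$stim, fx$spikes, fx$mos, fx$geom, "lnbrc",
                     config = fit_config(max_iter = c(60, 40, 30, 20),
                                         tol = 1e-8),
                     cells = cells)
  for (i in seq_along(cells)) {
    tru <- fx$enc$cells[[match(cells[i], fx$mos$cell_id)]]
    expect_gt(filter_cos_sim(fit$cells[[i]], tru, fx$geom), 0.75)
    obj <- fit$fit_report[[i]]$objective
    expect_true(all(diff(obj) <= 1e-6 * (abs(obj[-1]) + 1)))
  }
})

test_that("huge group penalty zeroes all coupling weights exactly", {
  fx <- fit_fixture()
  cid <- fx$mos$cell_id[3]
  fit <- fit_encoder(fx$stim, fx$spikes, fx$mos, fx$geom, "lnbrc",
                     config = fit_config(group_l21_weight = 1e4,
                                         max_iter = c(30, 20), rounds = 1),
                     cells = cid)
  expect_true(all(fit$cells[[1]]$coupling_weights == 0))
  # regularization path: spatial L0 nonincreasing in the L1 weight
  l0 <- vapply(c(1e-5, 3e-3, 3e-2), function(l1) {
    f <- fit_encoder(fx$stim, fx$spikes, fx$mos, fx$geom, "lnbrc",
                     config = fit_config(l1_weight = l1,
                                         max_iter = c(30, 20), rounds = 1),
                     cells = cid)
    sum(f$cells[[1]]$spatial_weights != 0)
  }, 0)
  expect_true(all(diff(l0) <= 0))
})

test_that("fitted coupled NLL nests below the uncoupled fit", {
  fx <- fit_fixture()
  cells <- fx$mos$cell_id[5:6]
  cfg <- fit_config(max_iter = c(60, 40, 30, 20))
  fc <- fit_encoder(fx$stim, fx$spikes, fx$mos, fx$geom, "lnbrc",
                    config = cfg, cells = cells)
  fu <- fit_encoder(fx$stim, fx$spikes, fx$mos, fx$geom, "lnbr",
                    config = cfg, cells = cells)
  for (i in seq_along(cells)) {
    nc <- lnbrc_nll(fc, fx$stim, fx$spikes, cells[i])
    nu <- lnbr_nll(fu, fx$stim, fx$spikes, cells[i])
    expect_lte(nc, nu + 1e-3 * abs(nu))
  }
})

test_that("LNP bias-only fit recovers the rate in closed form", {
  set.seed(75)
  geom <- encoder_geometry(32, 32, 11)
  mos <- build_mosaic(c(300, 300), spacings_um = c(ON_midget = 120),
                      jitter_fraction = 0, seed = 76)
  # bias-only world: gray stimulus, Poisson-ish spiking from an LNBRC with
  # no stimulus drive
  enc <- sample_ground_truth_params(mos, geom, seed = 77)
  for (i in seq_along(enc$cells)) {
    enc$cells[[i]]$spatial[] <- 0
    enc$cells[[i]]$temporal[] <- 0
    enc$cells[[i]]$feedback[] <- 0
    for (k in seq_along(enc$cells[[i]]$coupling)) enc$cells[[i]]$coupling[[k]][] <- 0
    enc$cells[[i]]$bias <- qlogis(0.025)
  }
  gray <- flashed_stimulus_set(lapply(1:240, function(k) {
    ret_image(matrix(0.5, 32, 32))
  }))  # 2 minutes = 14400 frames
  sp <- simulate_spikes(enc, gray, seed = 78)
  fit <- fit_encoder(gray, sp, mos, geom, "lnp",
                     config = fit_config(l1_weight = 0, max_iter = 100),
                     cells = mos$cell_id[1])
  b_hat <- fit$cells[[1]]$bias
  b_true <- log(0.025 * 25 / 3)  # counts per 8.33 ms frame
  expect_lt(abs(b_hat - b_true), 0.05)
})

test_that("grid search returns the best held-out point", {
  fx <- fit_fixture()
  grid1 <- data.frame(l1_weight = 2e-4, group_l21_weight = 1e-3)
  g1 <- grid_search_hyperparams(fx$stim, fx$spikes, fx$mos, fx$geom,
                                grid1, cells_per_type = 1,
                                config = fit_config(max_iter = c(40, 25),
                                                    rounds = 1), seed = 79)
  expect_equal(g1$best, grid1)
  expect_length(g1$scores, 1)
  # default sampling: 4 cells per type
  expect_equal(formals(grid_search_hyperparams)$cells_per_type, 4)
  grid3 <- data.frame(l1_weight = c(2e-4, 1000), group_l21_weight = 1e-3)
  g3 <- grid_search_hyperparams(fx$stim, fx$spikes, fx$mos, fx$geom,
                                grid3, cells_per_type = 1,
                                config = fit_config(max_iter = c(60, 40, 30, 20)),
                                seed = 79)
  # the extreme corner (an L1 heavy enough to kill the stimulus filter)
  # never wins against a moderate weight
  expect_lt(g3$scores[1], g3$scores[2])
  expect_equal(g3$best$l1_weight, 2e-4)
  expect_error(grid_search_hyperparams(fx$stim, fx$spikes, fx$mos,
                                       fx$geom, grid3[0, ]), "empty")
})

test_that("fraction of PSTH variance explained behaves at its limits", {
  fx <- fit_fixture()
  one_img <- flashed_stimulus_set(fx$stim$images[1])
  reps10 <- simulate_repeats(fx$enc, one_img, 10, seed = 80)
  reps60 <- simulate_repeats(fx$enc, one_img, 60, seed = 83)
  fv10 <- fraction_psth_variance_explained(fx$enc, one_img, reps10, seed = 81,
                                           n_model_repeats = 80)
  fv60 <- fraction_psth_variance_explained(fx$enc, one_img, reps60, seed = 81,
                                           n_model_repeats = 80)
  # generating model: value grows toward 1 as repeats increase
  expect_gt(mean(fv60, na.rm = TRUE), mean(fv10, na.rm = TRUE))
  expect_gt(mean(fv60, na.rm = TRUE), 0.4)
  # a rate-only (flat) model explains less than the generating model
  flat <- fx$enc
  for (i in seq_along(flat$cells)) {
    flat$cells[[i]]$spatial[] <- 0
    flat$cells[[i]]$temporal[] <- 0
  }
  fv0 <- fraction_psth_variance_explained(flat, one_img, reps60, seed = 82,
                                          n_model_repeats = 80)
  expect_lt(mean(fv0, na.rm = TRUE), mean(fv60, na.rm = TRUE))
  expect_error(fraction_psth_variance_explained(fx$enc, one_img, reps60[1]),
               "2 repeats")
})
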