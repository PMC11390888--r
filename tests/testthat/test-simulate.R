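test_that("ground-truth encoders have the stated structure", {
  enc <- small_encoder()
  mos <- small_mosaic()
  # bias closed form: sigmoid(b) = target rate per 1 ms bin
  expect_equal(plogis(enc$cells[[1]]$bias), 0.02, tolerance = 1e-12)
  geom <- small_geom()
  for (idx in c(1, 10, 30)) {
    cl <- enc$cells[[idx]]
    pol <- if (grepl("^ON", cl$cell_type)) 1 else -1
    # polarity at the RF center pixel matches cell type (the crop itself may
    # be clipped at the image border, so index by the true center)
    cy <- round(retinacode:::um_to_px(mos$y_um[match(cl$cell_id, mos$cell_id)], geom))
    cx <- round(retinacode:::um_to_px(mos$x_um[match(cl$cell_id, mos$cell_id)], geom))
    expect_gt(pol * cl$spatial[match(cy, cl$crop_rows),
                               match(cx, cl$crop_cols)], 0)
    # feedback negative at short lags (refractoriness)
    expect_lt(max(cl$feedback[1:3]), 0)
    # temporal kernel biphasic: opposite-sign lobes
    expect_lt(min(cl$temporal) * max(cl$temporal), 0)
  }
  # coupling strongest between homotypic neighbours (mean peak amplitude)
  homo <- c(); hetero <- c()
  for (cl in enc$cells) {
    ty <- cl$cell_type
    for (k in seq_along(cl$neighbors)) {
      jt <- mos$cell_type[match(cl$neighbors[k], mos$cell_id)]
      pk <- max(abs(cl$coupling[[k]]))
      if (jt == ty) homo <- c(homo, pk) else hetero <- c(hetero, pk)
    }
  }
  expect_gt(mean(homo), 2 * mean(hetero))
})

test_that("simulated spiking matches its Bernoulli law and timing structure", {
  enc <- small_encoder()
  # all filters zero, b = logit(0.1): empirical rate within binomial CI
  enc0 <- enc
  for (i in seq_along(enc0$cells)) {
    enc0$cells[[i]]$spatial[] <- 0
    enc0$cells[[i]]$temporal[] <- 0
    enc0$cells[[i]]$feedback[] <- 0
    for (k in seq_along(enc0$cells[[i]]$coupling)) {
      enc0$cells[[i]]$coupling[[k]][] <- 0
    }
    enc0$cells[[i]]$bias <- qlogis(0.1)
  }
  gray <- flashed_stimulus_set(lapply(1:4, function(k) {
    ret_image(matrix(0.5, 32, 32))
  }))
  sp0 <- simulate_spikes(enc0, gray, seed = 21)
  n_bins <- length(sp0)
  expect_lt(abs(mean(sp0) - 0.1), 3 * sqrt(0.1 * 0.9 / n_bins))

  # gray movie at default parameters: rate near (below) the 20 Hz target
  spg <- simulate_spikes(enc, gray, seed = 22)
  expect_gt(1000 * mean(spg), 10)
  expect_lt(1000 * mean(spg), 25)

  # reproducibility
  expect_identical(unclass(simulate_spikes(enc, gray, seed = 23)),
                   unclass(simulate_spikes(enc, gray, seed = 23)))

  # refractory dip in the autocorrelogram at 1-2 ms
  stim <- flashed_stimulus_set(texture_corpus(40))
  reps <- simulate_repeats(enc, stim, 2, seed = 24)
  cc <- cross_correlogram(reps, 1, 1, 5, shift_correct = FALSE)
  expect_lt(cc[["1"]] + cc[["2"]], 0.2 * cc[["0"]])

  expect_error(simulate_spikes(enc, stim, mode = "conditioned"),
               "conditioning")
})

test_that("network mode with zero coupling equals independent simulation", {
  enc <- small_encoder()
  encz <- enc
  for (i in seq_along(encz$cells)) {
    for (k in seq_along(encz$cells[[i]]$coupling)) {
      encz$cells[[i]]$coupling[[k]][] <- 0
    }
  }
  stim <- flashed_stimulus_set(texture_corpus(8))
  a <- simulate_spikes(encz, stim, mode = "network", seed = 31)
  # independent per-cell simulation: remove all neighbours entirely
  enci <- encz
  for (i in seq_along(enci$cells)) {
    enci$cells[[i]]$neighbors <- integer(0)
    enci$cells[[i]]$coupling <- list()
  }
  b <- simulate_spikes(enci, stim, mode = "network", seed = 31)
  expect_identical(unclass(a), unclass(b))
})

test_that("causality: spikes at <= t unchanged by stimulus changes after t", {
  enc <- small_encoder()
  imgs1 <- texture_corpus(4)
  imgs2 <- imgs1
  imgs2[[4]] <- generate_texture_image(777, 32, 32)  # change only trial 4
  a <- simulate_spikes(enc, flashed_stimulus_set(imgs1), seed = 41)
  b <- simulate_spikes(enc, flashed_stimulus_set(imgs2), seed = 41)
  bins_123 <- seq_len(3 * 500)
  expect_identical(unclass(a)[, bins_123], unclass(b)[, bins_123])
})

test_that("conditioned-mode likelihood prefers the generating encoder", {
  enc <- small_encoder()
  stim <- flashed_stimulus_set(texture_corpus(30))
  cond <- simulate_spikes(enc, stim, mode = "network", seed = 51)
  sim <- simulate_spikes(enc, stim, mode = "conditioned", seed = 52,
                         conditioning_spikes = cond)
  # perturbed encoder: filters scaled x 0.5
  encp <- enc
  for (i in seq_along(encp$cells)) {
    encp$cells[[i]]$spatial <- encp$cells[[i]]$spatial * 0.5
    encp$cells[[i]]$feedback <- encp$cells[[i]]$feedback * 0.5
  }
  cells <- attr(sim, "cell_ids")[1:8]
  d <- vapply(cells, function(cid) {
    lnbrc_nll(encp, stim, sim, cid) - lnbrc_nll(enc, stim, sim, cid)
  }, 0)
  expect_gt(mean(d), 0)  # true encoder has lower NLL on average
})

test_that("repeat PSTH tracks the sigmoid(g) rate profile", {
  enc <- small_encoder()
  img <- generate_texture_image(4001, 32, 32)
  stim <- flashed_stimulus_set(list(img))
  reps <- simulate_repeats(enc, stim, 150, seed = 61)
  p <- psth(reps)
  # expected rate profile: sigmoid of the generator signal, averaged over an
  # independent set of repeats (the history terms differ per repeat)
  reps2 <- simulate_repeats(enc, stim, 80, seed = 62)
  k <- retinacode:::gaussian_kernel_1d(2)
  smooth_same <- function(v) {
    r <- (length(k) - 1) / 2
    padded <- c(numeric(r), v, numeric(r))
    vapply(seq_along(v), function(t) sum(k * padded[t:(t + 2 * r)]), 0)
  }
  profiles <- vapply(1:8, function(i) {
    smooth_same(rowMeans(vapply(reps2, function(r) {
      sigmoid(generator_signal(enc, stim, r, attr(r, "cell_ids")[i]))
    }, numeric(ncol(reps2[[1]])))))
  }, numeric(ncol(reps2[[1]])))
  # evaluate on modulated cells (correlation is meaningless for cells the
  # stimulus barely drives)
  modulated <- order(apply(profiles, 2, sd), decreasing = TRUE)[1:4]
  cors <- vapply(modulated, function(i) cor(p[i, ], profiles[, i]), 0)
  expect_gt(mean(cors), 0.9)
})
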