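test_that("valid region is the rasterized convex hull of the RF disks", {
  geom <- encoder_geometry(32, 32, 11)
  # three cells at triangle corners with tiny radius: filled triangle
  tri <- structure(data.frame(cell_id = 1:3, cell_type = "ON_midget",
                              y_um = c(55, 55, 297), x_um = c(55, 297, 176),
                              radius_um = 0.1),
                   field_size_um = c(352, 352),
                   class = c("rgc_mosaic", "data.frame"))
  m <- valid_region(tri, geom)
  expect_true(m[10, 16])            # inside
  expect_false(m[30, 2])            # outside corner
  # brute-force oracle: point is in the hull iff adding it leaves chull alone
  verts <- cbind(y = um_to_px(tri$y_um, geom), x = um_to_px(tri$x_um, geom))
  for (p in list(c(6, 6), c(20, 16), c(31, 31), c(5, 25))) {
    inside_oracle <- length(chull(rbind(verts[, 2], p[2]),
                                  rbind(verts[, 1], p[1]))) ==
      length(chull(c(verts[, 2], p[2]), c(verts[, 1], p[1]))) &&
      !(4 %in% chull(c(verts[, 2], p[2]), c(verts[, 1], p[1])))
    expect_equal(unname(m[p[1], p[2]]), inside_oracle)
  }
  # monotone in radius
  tri2 <- tri; tri2$radius_um <- 40
  expect_gte(sum(valid_region(tri2, geom)), sum(m))
  expect_error(valid_region(tri[1:2, ], geom), "3 cells")
})

test_that("masked MS-SSIM recovers shifts and matches an independent oracle", {
  img <- unclass(generate_texture_image(21, 32, 32))
  mask <- matrix(TRUE, 32, 32)
  expect_equal(ms_ssim_masked(img, img, mask)$score, 1, tolerance = 1e-9)
  # symmetry at shift 0 and boundedness
  other <- unclass(generate_texture_image(22, 32, 32))
  a <- ms_ssim_masked(img, other, mask)$score
  b <- ms_ssim_masked(other, img, mask)$score
  expect_equal(a, b, tolerance = 1e-9)
  expect_true(a >= 0 && a <= 1)
  # circular-shift recovery
  shifted <- img[c(30:32, 1:29), c(31:32, 1:30)]  # content moved by (+3, +2)
  res <- ms_ssim_masked(shifted, img, mask, max_shift_px = 4)
  # returned shift is the offset applied to the recon to best match truth
  expect_equal(res$shift, c(-3, -2))
  inner <- matrix(FALSE, 32, 32); inner[8:25, 8:25] <- TRUE
  expect_gt(ms_ssim_masked(shifted, img, inner, max_shift_px = 4)$score, 0.99)
  # single-scale component matches the naive double-loop oracle
  x <- unclass(generate_texture_image(23, 24, 24))
  y <- 0.7 * x + 0.1 + matrix(rnorm(576, sd = 0.03), 24, 24)
  maps <- retinacode:::ssim_maps(x, y)
  expect_lt(abs(mean(maps$ssim) - oracle_ssim_mean(x, y)), 1e-4)
  expect_error(ms_ssim_masked(img, img, matrix(FALSE, 32, 32)), "mask")
})

test_that("PSTH is a normalized smoothed mean over repeats", {
  # single repeat, single spike: Gaussian bump integrating to one spike
  s <- matrix(0L, 1, 200); s[1, 100] <- 1L
  p <- psth(list(spike_trains(s)), kernel_sd_ms = 2)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_equal(which.max(p[1, ]), 100)
  # conservation: sum over bins = mean spike count per repeat
  set.seed(5)
  reps <- lapply(1:4, function(r) {
    m <- matrix(0L, 2, 300)
    m[cbind(sample(1:2, 12, TRUE), sample(20:280, 12))] <- 1L
    spike_trains(m)
  })
  p2 <- psth(reps)
  counts <- Reduce(`+`, lapply(reps, rowSums)) / 4
  expect_equal(rowSums(p2), counts, tolerance = 1e-6)
  # homogeneous Bernoulli repeats: flat at p within binomial error
  set.seed(6)
  reps3 <- lapply(1:200, function(r) spike_trains(matrix(rbinom(500, 1, 0.05), 1)))
  p3 <- psth(reps3)
  expect_lt(abs(mean(p3) - 0.05), 3 * sqrt(0.05 * 0.95 / (200 * 500)))
  expect_lt(max(abs(p3[50:450] - 0.05)), 6 * sqrt(0.05 * 0.95 / 200 / 3))
})

test_that("cross-correlograms and the shift predictor behave as planted", {
  set.seed(7)
  T <- 2000
  # independent homogeneous trains: corrected correlogram ~ 0
  reps <- lapply(1:40, function(r) {
    spike_trains(matrix(rbinom(2 * T, 1, 0.03), 2))
  })
  cc <- cross_correlogram(reps, 1, 2, 20)
  expect_lt(max(abs(cc)), 5 * sd(cc) + 1e-9)
  expect_lt(abs(mean(cc)), 0.5)
  # a vs a at lag 0, no correction: the spike count
  one <- list(reps[[1]])
  cca <- cross_correlogram(one, 1, 1, 5, shift_correct = FALSE)
  expect_equal(unname(cca["0"]), sum(reps[[1]][1, ]))
  # planted 3 ms co-firing survives correction at > 5 sigma
  reps2 <- lapply(1:200, function(r) {
    a <- rbinom(T, 1, 0.02)
    b <- rbinom(T, 1, 0.01)
    idx <- which(a == 1 & seq_len(T) <= T - 3)
    planted <- idx[rbinom(length(idx), 1, 0.4) == 1] + 3
    b[planted] <- 1
    spike_trains(rbind(a, b))
  })
  cc2 <- cross_correlogram(reps2, 1, 2, 10)
  noise_sd <- sd(cc2[names(cc2) != "3"])
  expect_gt(cc2[["3"]], 5 * noise_sd)
  expect_error(cross_correlogram(reps[1], 1, 2, 10), "2 repeats")
  expect_error(cross_correlogram(reps, 1, 2, 5000), "exceeds")
})

test_that("spike-time perturbation clips, collapses, and matches N(0, sigma^2)", {
  set.seed(8)
  s <- spike_trains(matrix(rbinom(3 * 1000, 1, 0.04), 3))
  expect_identical(perturb_spike_times(s, 0), s)
  for (sig in c(1, 2, 5, 10, 20, 40)) {   # supported experimental grid
    p <- perturb_spike_times(s, sig, seed = sig)
    expect_true(all(p %in% c(0L, 1L)))
    expect_lte(sum(p), sum(s))
  }
  # KS test of the realized shift distribution on a single long sparse train
  set.seed(9)
  T <- 2e5
  tt <- sort(sample(seq(50, T - 50), 1e4))
  tt <- tt[c(TRUE, diff(tt) > 25)]  # isolated spikes so shifts are identifiable
  s2 <- matrix(0L, 1, T); s2[1, tt] <- 1L
  p2 <- perturb_spike_times(spike_trains(s2), 5, seed = 10)
  tnew <- which(p2[1, ] == 1)
  # match each new spike to its nearest original spike
  shifts <- vapply(tnew, function(t) t - tt[which.min(abs(tt - t))], 0)
  ks <- ks.test(shifts + runif(length(shifts), -0.5, 0.5), "pnorm", 0, 5)
  expect_gt(ks$p.value, 0.01)
})

test_that("repeat shuffling preserves marginals and kills noise correlations", {
  set.seed(10)
  T <- 1500
  # planted noise correlation: shared per-trial gain
  reps <- lapply(1:60, function(r) {
    gain <- sample(c(0.5, 2), 1)
    spike_trains(rbind(rbinom(T, 1, 0.02 * gain), rbinom(T, 1, 0.02 * gain)))
  })
  sh <- shuffle_repeats(reps, seed = 11)
  # per-cell PSTH and totals preserved exactly
  expect_equal(psth(sh), psth(reps), tolerance = 1e-12)
  tot <- function(rs, i) sort(vapply(rs, function(m) sum(m[i, ]), 0))
  expect_identical(tot(sh, 1), tot(reps, 1))
  expect_identical(tot(sh, 2), tot(reps, 2))
  # planted correlation removed: corrected zero-lag peak drops
  cc_raw <- cross_correlogram(reps, 1, 2, 5)
  cc_sh <- cross_correlogram(sh, 1, 2, 5)
  expect_gt(sum(cc_raw), 5 * max(sd(cc_sh), 1e-3))
  expect_lt(abs(sum(cc_sh)), 0.6 * sum(cc_raw))
  expect_error(shuffle_repeats(reps[1]), "2 repeats")
})

test_that("drift magnitude and eye-position error follow their conventions", {
  expect_equal(realized_drift_magnitude(zero_trajectory(30)), 0)
  ramp <- cbind(seq(-20, 20, length.out = 41), 0)
  expect_equal(realized_drift_magnitude(ramp), sd(ramp[, 1]))
  # Monte-Carlo quantile oracle at D = 10, 60 frames
  set.seed(12)
  mags <- vapply(1:1500, function(r) {
    realized_drift_magnitude(simulate_drift_trajectory(60, 10))
  }, 0)
  oracle <- vapply(1:1500, function(r) {
    inc <- matrix(rnorm(118, sd = sqrt(20)), ncol = 2)
    pos <- rbind(c(0, 0), apply(inc, 2, cumsum))
    sqrt(sum(apply(pos, 2, var)))
  }, 0)
  for (q in c(0.25, 0.5, 0.75)) {
    expect_lt(abs(quantile(mags, q) - quantile(oracle, q)) /
                quantile(oracle, q), 0.08)
  }
  # eye error: exact zero on truth, gauge invariant, zero-model ~ oracle
  tr <- simulate_drift_trajectory(60, 10, seed = 13)
  expect_equal(eye_position_error(tr, tr$displacements_um)$mean, 0)
  offs <- sweep(tr$displacements_um, 2, c(55, -31))
  expect_equal(eye_position_error(tr, offs)$mean, 0, tolerance = 1e-9)
  expect_error(eye_position_error(tr, matrix(0, 10, 2)), "lengths")
  set.seed(14)
  zerr <- vapply(1:500, function(r) {
    t2 <- simulate_drift_trajectory(60, 10)
    eye_position_error(t2, matrix(0, 60, 2))$mean
  }, 0)
  # Brownian oracle for the mean-gauge zero-model error
  orc <- vapply(1:500, function(r) {
    inc <- matrix(rnorm(118, sd = sqrt(20)), ncol = 2)
    pos <- rbind(c(0, 0), apply(inc, 2, cumsum))
    pos <- sweep(pos, 2, colMeans(pos))
    mean(sqrt(rowSums(pos^2)))
  }, 0)
  se <- sqrt(var(zerr) / 500 + var(orc) / 500)
  expect_lt(abs(mean(zerr) - mean(orc)), 3 * se)
})
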