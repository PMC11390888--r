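test_that("texture images have the requested spectral slope and are deterministic", {
  img <- generate_texture_image(11, 64, 64, spectral_exponent = 2)
  expect_s3_class(img, "ret_image")
  expect_true(all(img >= 0 & img <= 1))
  # log-log regression of the radial power spectrum (independent FFT check)
  f <- radial_frequency_grid(64, 64)
  P <- Mod(fft(unclass(img) - mean(img)))^2
  sel <- f > 2 & f < 24
  slope <- coef(lm(log(P[sel]) ~ log(f[sel])))[2]
  expect_lt(abs(slope - (-2)), 0.2)

  # exponent 0: flat spectrum within sampling error
  img0 <- generate_texture_image(12, 64, 64, spectral_exponent = 0)
  P0 <- Mod(fft(unclass(img0) - mean(img0)))^2
  slope0 <- coef(lm(log(P0[sel]) ~ log(f[sel])))[2]
  expect_lt(abs(slope0), 0.2)

  expect_identical(unclass(generate_texture_image(7, 32, 32)),
                   unclass(generate_texture_image(7, 32, 32)))
  expect_error(generate_texture_image(1, 8, 32), "16")
})

test_that("drift trajectories follow MSD = 4Dt and discretize by rounding", {
  tr0 <- simulate_drift_trajectory(30, 0, seed = 1)
  expect_true(all(tr0$displacements_um == 0))
  expect_true(all(tr0$displacements_px == 0))
  expect_error(simulate_drift_trajectory(10, -1), "diffusion")

  # Monte-Carlo oracle at the experimental D = 10 um^2/frame, 60 frames
  set.seed(99)
  D <- 10; nF <- 60; nrep <- 4000
  msd_frames <- c(10, 30, 60)
  sq <- matrix(0, nrep, length(msd_frames))
  for (r in seq_len(nrep)) {
    inc <- matrix(rnorm(2 * (nF - 1), sd = sqrt(2 * D)), ncol = 2)
    pos <- apply(inc, 2, cumsum)
    sq[r, ] <- rowSums(pos[msd_frames - 1, ]^2)
  }
  # package trajectories against the oracle mean within 3 SE
  set.seed(100)
  pk <- matrix(0, 2000, length(msd_frames))
  for (r in seq_len(2000)) {
    tr <- simulate_drift_trajectory(nF, D)
    pk[r, ] <- rowSums(tr$displacements_um[msd_frames, ]^2)
  }
  for (j in seq_along(msd_frames)) {
    expected <- 4 * D * (msd_frames[j] - 1)  # frame 1 is at the origin
    se <- sd(pk[, j]) / sqrt(nrow(pk))
    expect_lt(abs(mean(pk[, j]) - expected), 3 * se + 0.02 * expected)
    # oracle agrees with the closed form too
    expect_lt(abs(mean(sq[, j]) - expected) / expected, 0.05)
  }

  # infinite pitch: integer path collapses to zero while um path does not
  tr <- simulate_drift_trajectory(40, 10, pixel_pitch_um = 1e9, seed = 5)
  expect_true(all(tr$displacements_px == 0))
  expect_gt(max(abs(tr$displacements_um)), 0)

  # integer path equals rounded um path (ties toward zero)
  tr2 <- simulate_drift_trajectory(40, 10, pixel_pitch_um = 11, seed = 6)
  manual <- sign(tr2$displacements_um / 11) *
    ceiling(abs(tr2$displacements_um / 11) - 0.5)
  expect_identical(tr2$displacements_px, manual)
})

test_that("flashed trials have the experimental frame counts", {
  img <- generate_texture_image(3, 32, 32)
  strip <- function(m) matrix(as.numeric(m), nrow(m))
  mv <- render_flashed_trial(img, flash_ms = 100, gray_ms = 400)
  expect_equal(dim(mv$frames)[3], 60)  # 12 image + 48 gray frames at 120 Hz
  expect_equal(mv$frames[, , 12], strip(img))
  expect_true(all(mv$frames[, , 13:60] == 0.5))

  mv2 <- render_flashed_trial(img, flash_ms = 100, gray_ms = 0)
  expect_equal(dim(mv2$frames)[3], 12)
  expect_true(all(apply(mv2$frames, 3, function(f) all(f == strip(img)))))

  gray_img <- ret_image(matrix(0.5, 32, 32))
  mv3 <- render_flashed_trial(gray_img, 100, 400)
  expect_true(all(mv3$frames == 0.5))

  expect_error(render_flashed_trial(img, flash_ms = 101, gray_ms = 400),
               "multiple")
})

test_that("jittered rendering translates frames and is equivariant", {
  img <- generate_texture_image(8, 32, 32)
  zero <- zero_trajectory(60)
  mv <- render_jittered_trial(img, zero)
  expect_equal(dim(mv$frames)[3], 60)
  strip <- function(m) matrix(as.numeric(m), nrow(m))
  expect_true(all(apply(mv$frames, 3, function(f) all(f == strip(img)))))

  # translation by construction: a step edge moves by one column
  edge <- matrix(0, 32, 32); edge[, 16:32] <- 1
  shifted <- shift_image(edge, c(0, 1))
  expect_true(all(shifted[, 17:32] == 1))
  expect_true(all(shifted[, 2:16] == 0))
  expect_true(all(shifted[, 1] == 0.5))  # exposed border is background

  # round-trip: phase-correlation registration recovers the offset
  tr <- simulate_drift_trajectory(10, 40, seed = 12)
  mvj <- render_jittered_trial(img, tr)
  for (t in c(5, 10)) {
    a <- mvj$frames[, , 1]; b <- mvj$frames[, , t]
    xc <- Re(fft(fft(b - mean(b)) * Conj(fft(a - mean(a))), inverse = TRUE))
    pk <- which(xc == max(xc), arr.ind = TRUE)[1, ]
    est <- ((pk - 1 + 16) %% 32) - 16
    expect_equal(unname(est), unname(tr$displacements_px[t, ]))
  }

  # equivariance away from borders
  base <- unclass(img)
  tr1 <- simulate_drift_trajectory(6, 10, seed = 13)
  m1 <- render_jittered_trial(ret_image(shift_image(base, c(1, 0))), tr1)
  m2 <- render_jittered_trial(img, tr1)
  for (t in 1:6) {
    o <- tr1$displacements_px[t, ]
    interior_r <- 6:26; interior_c <- 6:26
    expect_equal(m1$frames[interior_r, interior_c, t],
                 shift_image(m2$frames[, , t], c(1, 0))[interior_r, interior_c])
  }
  expect_true(all(mvj$frames >= 0 & mvj$frames <= 1))

  big <- zero_trajectory(3)
  big$displacements_px[2, ] <- c(40, 0)
  expect_error(render_jittered_trial(img, big), "exceeds")
})
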