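# Reconstruction machinery on a small synthetic retina. Deeper end-to-end
# quality properties live in test-acceptance.R.

recon_fixture <- function() {
  memo_fixture("recon_fixture", function() {
    geom <- small_geom()
    mos <- small_mosaic()
    enc <- small_encoder()
    img <- generate_texture_image(91, 32, 32)
    stim <- flashed_stimulus_set(list(img))
    spikes <- simulate_spikes(enc, stim, seed = 92)
    timing <- trial_timing("flash", 60)
    list(geom = geom, mos = mos, enc = enc, img = img, spikes = spikes,
         timing = timing, ctx = recon_context(enc, spikes, timing))
  })
}

test_that("encoding step solves its sub-problem", {
  fx <- recon_fixture()
  z <- matrix(0.45, 32, 32)
  # quadratic domination: rho -> Inf pins x to z
  big <- encoding_step(fx$ctx, z, rho = 1e6, maxit = 50)
  expect_lt(max(abs(big$x - z)), 1e-3)
  # optimality: small gradient norm, objective at x below objective at z
  st <- encoding_step(fx$ctx, z, rho = 1, maxit = 200)
  expect_lt(st$grad_norm, 1e-2 * (1 + abs(st$value)))
  obj_at <- function(y) {
    retinacode:::recon_nll_grad(fx$ctx, y, list(matrix(0L, 60, 2)), 1,
                                grad = FALSE)$nll + 0.5 * sum((y - z)^2)
  }
  expect_lte(st$value, obj_at(z))
  # scalar-calculus oracle: a single bias-only cell makes the likelihood flat
  # in the image, so the sub-problem minimizer is exactly z
  enc1 <- fx$enc
  enc1$cells <- enc1$cells[1]
  enc1$cells[[1]]$spatial[] <- 0
  enc1$cells[[1]]$neighbors <- integer(0)
  enc1$cells[[1]]$coupling <- list()
  sp1 <- spike_trains(unclass(fx$spikes)[1, , drop = FALSE],
                      attr(fx$spikes, "cell_ids")[1])
  ctx1 <- recon_context(enc1, sp1, fx$timing)
  st1 <- encoding_step(ctx1, z, rho = 2, maxit = 100)
  expect_lt(max(abs(st1$x - z)), 1e-6)
  expect_error(encoding_step(fx$ctx, z, rho = 0), "rho")
})

test_that("translation gauge: shifting image and trajectory together leaves the likelihood unchanged", {
  fx <- recon_fixture()
  timing <- trial_timing("drift", 60)
  tr <- simulate_drift_trajectory(60, 10, seed = 93)
  stim <- drift_stimulus_set(list(fx$img), list(tr))
  sp <- simulate_spikes(fx$enc, stim, seed = 94)
  ctx <- recon_context(fx$enc, sp, timing)
  # image content confined to the interior so that small joint shifts of
  # image and trajectory are exact translations (no border effects)
  y <- matrix(0.5, 32, 32)
  y[7:26, 7:26] <- unclass(generate_texture_image(95, 32, 32))[7:26, 7:26]
  base <- retinacode:::recon_nll_grad(ctx, y, list(tr$displacements_px), 1,
                                      grad = FALSE)$nll
  for (off in list(c(1, 0), c(0, -2))) {
    y2 <- shift_image(y, off)
    tr2 <- sweep(tr$displacements_px, 2, off)
    shifted <- retinacode:::recon_nll_grad(ctx, y2, list(tr2), 1,
                                           grad = FALSE)$nll
    expect_lt(abs(shifted - base), 1e-8 * abs(base))
  }
})

test_that("splitting loop with exact prox matches the closed-form MAP (quadratic likelihood)", {
  set.seed(96)
  h <- 16; w <- 16; npx <- 256
  A <- matrix(rnorm(600 * npx, sd = 0.3), 600, npx)
  ytrue <- as.numeric(generate_texture_image(97, 16, 16))
  b <- as.numeric(A %*% (ytrue - 0.5)) + rnorm(600, sd = 0.3)
  lam <- 0.5
  pr <- one_over_f_prior(1, h, w)
  # closed-form oracle via the exact prior quadratic operator
  Q <- matrix(0, npx, npx)
  for (j in seq_len(npx)) {
    e <- matrix(0, h, w); e[j] <- 1
    Q[, j] <- as.numeric(one_over_f_neg_log_prior(e, pr)$gradient) / 2
  }
  map <- solve(crossprod(A) + 2 * lam * Q,
               crossprod(A, b) + crossprod(A) %*% rep(0.5, npx))
  ctx <- gaussian_likelihood_context(A, b, h, w)
  out <- run_splitting_loop(ctx, pr, rep(1, 10), lam, dual = TRUE)
  expect_lt(sqrt(mean((as.numeric(out$image) - map)^2)), 1e-3)
  # plain half-quadratic splitting tracks the MAP with an O(1/rho) bias
  out2 <- run_splitting_loop(ctx, pr, rho_schedule(1, 1e4, 10), lam)
  expect_lt(sqrt(mean((as.numeric(out2$image) - map)^2)), 5e-2)
})

test_that("1/F exact reconstruction agrees with splitting and has monotone trace", {
  fx <- recon_fixture()
  r1 <- reconstruct_1f_exact(fx$spikes, fx$enc, lambda = 30,
                             timing = fx$timing, max_iter = 2000, tol = 1e-6)
  expect_true(all(diff(r1$trace) <= 0))
  expect_true(all(is.finite(r1$image)))
  # splitting loop with the exact 1/F prox and a dual variable reaches the
  # same MAP
  out <- run_splitting_loop(fx$ctx, one_over_f_prior(1, 32, 32), rep(2, 80),
                            30, dual = TRUE, maxit_encoding = 200)
  expect_lt(sqrt(mean((out$image - r1$config$image_raw)^2)), 2e-3)
  # lambda -> Inf: estimate approaches a constant (prior-dominated)
  rb <- reconstruct_1f_exact(fx$spikes, fx$enc, lambda = 1e7,
                             timing = fx$timing, max_iter = 300)
  expect_lt(sd(rb$config$image_raw), 0.02)
})

test_that("flashed PnP reconstruction beats an information-ablated control", {
  fx <- recon_fixture()
  mask <- small_mask()
  den <- wiener_denoiser()
  res <- reconstruct_flashed_map(fx$spikes, fx$enc, den,
                                 rho_schedule(0.1, 10, 10), lambda = 0.2,
                                 mask = mask)
  expect_length(res$trace, 10)
  expect_true(all(res$image >= 0 & res$image <= 1))
  score <- ms_ssim_masked(res$image, unclass(fx$img), mask)$score
  # ablation: spikes from an encoder with zeroed stimulus filters carry no
  # image information
  enc0 <- fx$enc
  for (i in seq_along(enc0$cells)) enc0$cells[[i]]$spatial[] <- 0
  sp0 <- simulate_spikes(enc0, flashed_stimulus_set(list(fx$img)), seed = 98)
  res0 <- reconstruct_flashed_map(sp0, fx$enc, den, rho_schedule(0.1, 10, 10),
                                  lambda = 0.2, mask = mask)
  score0 <- ms_ssim_masked(res0$image, unclass(fx$img), mask)$score
  expect_gt(score, score0)
})

test_that("known-eye-movement reconstruction reduces to flashed-style at zero trajectory", {
  fx <- recon_fixture()
  timing <- trial_timing("drift", 60)
  tr <- simulate_drift_trajectory(60, 10, seed = 99)
  stim <- drift_stimulus_set(list(fx$img), list(tr))
  sp <- simulate_spikes(fx$enc, stim, seed = 100)
  pr <- one_over_f_prior(1, 32, 32)
  rz <- reconstruct_known_em(sp, fx$enc, pr, zero_trajectory(60),
                             rho_schedule(0.1, 10, 5), lambda = 0.3,
                             timing = timing, maxit_encoding = 30)
  # flashed-style loop on the same spikes with an all-visible zero trajectory
  ctx <- recon_context(fx$enc, sp, timing)
  ref <- run_splitting_loop(ctx, pr, rho_schedule(0.1, 10, 5), 0.3,
                            trajs = list(matrix(0L, 60, 2)), wts = 1,
                            maxit_encoding = 30)
  expect_equal(rz$image, pmin(pmax(ref$image, 0), 1), tolerance = 1e-10)
  expect_error(reconstruct_known_em(sp, fx$enc, pr,
                                    zero_trajectory(10), timing = timing),
               "length")
})

test_that("noiseless linear reconstruction satisfies its constraint exactly", {
  fx <- recon_fixture()
  M <- linear_projection_matrix(fx$enc)
  expect_equal(max(abs(colSums(M^2) - 1)), 0, tolerance = 1e-12)
  # truth inside span(M): exact recovery of the projection coefficients
  set.seed(101)
  y_in_span <- matrix(M %*% rnorm(ncol(M), sd = 0.1) + 0.5, 32, 32)
  s_obs <- as.numeric(crossprod(M, as.numeric(y_in_span)))
  pr <- one_over_f_prior(1, 32, 32)
  res <- reconstruct_noiseless_linear(s_obs, M, pr, rho_schedule(0.1, 10, 10),
                                      lambda = 0)
  expect_lt(res$config$residual_inf, 1e-8)
  expect_lt(max(abs(crossprod(M, as.numeric(res$image)) - s_obs)), 1e-8)
  # lambda = 0 and start at gray: solution is the min-norm-from-gray point,
  # which equals y_in_span here
  expect_lt(max(abs(res$image - y_in_span)), 1e-6)
  # projection idempotence
  G <- solve(crossprod(M))
  proj <- function(z) z - M %*% (G %*% (crossprod(M, z) - s_obs))
  z0 <- rnorm(1024)
  expect_equal(proj(proj(z0)), proj(z0), tolerance = 1e-9)
  # KKT oracle: equality-constrained quadratic prox agrees with solve()
  rho <- 2; ztgt <- rnorm(1024)
  x_pkg <- proj(ztgt)
  kkt <- solve(rbind(cbind(diag(1024) * rho, M),
                     cbind(t(M), matrix(0, ncol(M), ncol(M)))),
               c(rho * ztgt, s_obs))
  expect_lt(max(abs(x_pkg - kkt[1:1024])), 1e-7)
})

test_that("joint reconstruction returns a coherent result object", {
  fx <- recon_fixture()
  timing <- trial_timing("drift", 30)
  tr <- simulate_drift_trajectory(30, 10, seed = 102)
  stim <- drift_stimulus_set(list(fx$img), list(tr))
  sp <- simulate_spikes(fx$enc, stim, seed = 103)
  den <- wiener_denoiser()
  res <- reconstruct_joint_em(sp, fx$enc, den, timing, lambda = 0.15,
                              mask = small_mask(), seed = 104,
                              n_particles = 8, n_em = 1, n_restarts = 1)
  expect_s3_class(res, "recon_result")
  expect_equal(dim(res$trajectory), c(30, 2))
  expect_equal(res$trajectory[1, ], c(0, 0), tolerance = 20)  # near origin
  expect_equal(sum(res$ensemble$weights), 1, tolerance = 1e-9)
  expect_true(all(res$image >= 0 & res$image <= 1))
})
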