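# Independent oracles: deliberately naive implementations used to freeze
# expected values. They share no code with the package's fast paths.

# brute-force triple-loop generator signal (Eq.-style direct sum)
oracle_generator_signal <- function(encoder, movie, spikes, cell_idx) {
  cl <- encoder$cells[[cell_idx]]
  T <- ncol(spikes)
  fp <- movie$frame_period_ms
  nF <- dim(movie$frames)[3]
  # per-frame projection, naive double loop
  proj <- numeric(nF)
  for (f in seq_len(nF)) {
    acc <- 0
    for (r in seq_along(cl$crop_rows)) {
      for (cc in seq_along(cl$crop_cols)) {
        acc <- acc + cl$spatial[r, cc] *
          (movie$frames[cl$crop_rows[r], cl$crop_cols[cc], f] - 0.5)
      }
    }
    proj[f] <- acc
  }
  frame_at <- floor((seq_len(T) - 1) / fp) + 1
  g <- rep(cl$bias, T)
  for (t in seq_len(T)) {
    for (tau in seq_along(cl$temporal)) {
      u <- t - tau
      if (u >= 1) g[t] <- g[t] + cl$temporal[tau] * proj[frame_at[u]]
    }
    for (tau in seq_along(cl$feedback)) {
      u <- t - tau
      if (u >= 1) g[t] <- g[t] + cl$feedback[tau] * spikes[cell_idx, u]
    }
    for (k in seq_along(cl$neighbors)) {
      j <- cl$neighbors[k]
      for (tau in seq_along(cl$coupling[[k]])) {
        u <- t - tau
        if (u >= 1) g[t] <- g[t] + cl$coupling[[k]][tau] * spikes[j, u]
      }
    }
  }
  g
}

oracle_bernoulli_nll <- function(g, s) {
  # Bernoulli log-pmf via R's own stable primitives (independent of the
  # package's log1pexp formulation)
  -sum(dbinom(s, 1, plogis(g), log = TRUE))
}

# naive SSIM with the same Gaussian window definition but direct O(n^2 k^2)
# loops and explicit border normalization
oracle_ssim_mean <- function(x, y, sigma = 1.5, radius = 5,
                             C1 = 0.01^2, C2 = 0.03^2) {
  h <- nrow(x); w <- ncol(x)
  k1 <- dnorm(-radius:radius, sd = sigma)
  ssim_vals <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      wins <- 0; mx <- 0; my <- 0; sxx <- 0; syy <- 0; sxy <- 0
      for (dr in -radius:radius) {
        for (dc in -radius:radius) {
          rr <- r + dr; c2 <- cc + dc
          if (rr < 1 || rr > h || c2 < 1 || c2 > w) next
          wt <- k1[dr + radius + 1] * k1[dc + radius + 1]
          wins <- wins + wt
          mx <- mx + wt * x[rr, c2]; my <- my + wt * y[rr, c2]
          sxx <- sxx + wt * x[rr, c2]^2; syy <- syy + wt * y[rr, c2]^2
          sxy <- sxy + wt * x[rr, c2] * y[rr, c2]
        }
      }
      mx <- mx / wins; my <- my / wins
      sxx <- sxx / wins - mx^2; syy <- syy / wins - my^2
      sxy <- sxy / wins - mx * my
      ssim_vals[r, cc] <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
        ((mx^2 + my^2 + C1) * (sxx + syy + C2))
    }
  }
  mean(ssim_vals)
}

# scalar Kalman filter for the 1D linear-Gaussian surrogate
oracle_kalman <- function(obs, q_var, r_var, m0 = 0, v0 = 0) {
  n <- length(obs)
  m <- numeric(n); v <- numeric(n)
  mp <- m0; vp <- v0
  for (t in seq_len(n)) {
    vp_pred <- vp + q_var
    K <- vp_pred / (vp_pred + r_var)
    mp <- mp + K * (obs[t] - mp)
    vp <- (1 - K) * vp_pred
    m[t] <- mp; v[t] <- vp
  }
  list(mean = m, var = v)
}
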