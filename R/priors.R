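## Image log-priors and their proximal / denoising steps.
##
## Three interchangeable priors drive the plug-and-play reconstruction loop:
## the exact 1/F spectral Gaussian prior (natural-image power spectrum), a
## general Fourier-diagonal Gaussian prior with closed-form proximal operator
## (used as a test oracle), and a trainable stand-in denoiser prior exposing
## the (noisy image, noise sd, valid mask) -> denoised image contract.

#' 1/F spectral Gaussian image prior
#'
#' Negative log-prior `lambda * sum_k |a_k(y)|^2 / f_k^2` over nonzero
#' frequencies, where `a_k` is the unitary-FFT Fourier amplitude and `f_k`
#' the radial frequency in cycles/image. The DC term is excluded (its 1/f^2
#' weight would be infinite); the mean luminance is left to the likelihood.
#'
#' @param lambda_weight prior weight (>= 0).
#' @param height,width image size the prior is instantiated for.
#' @return list of class `one_over_f_prior`.
#' @export
one_over_f_prior <- function(lambda_weight = 1, height, width) {
  check_scalar(lambda_weight, "lambda_weight", lower = 0)
  f <- radial_frequency_grid(height, width)
  w <- 1 / f^2
  w[1, 1] <- 0  # DC excluded
  structure(list(lambda = lambda_weight, freq_weight = w,
                 height = height, width = width),
            class = c("one_over_f_prior", "image_prior"))
}

#' Evaluate the 1/F negative log-prior and its gradient
#'
#' Uses the unitary FFT normalization `a_k = fft(y)[k] / sqrt(n_pixels)`.
#' The gradient is the exact linear operator `2 * lambda * IFFT(W * FFT(y))`
#' with `W = 1/f^2` (0 at DC).
#'
#' @param image numeric matrix.
#' @param prior a [one_over_f_prior()] matching the image size.
#' @return list with `value` (scalar) and `gradient` (matrix).
#' @export
one_over_f_neg_log_prior <- function(image, prior) {
  stopifnot(nrow(image) == prior$height, ncol(image) == prior$width)
  npx <- length(image)
  Y <- fft(unclass(image)) / sqrt(npx)
  value <- prior$lambda * sum(prior$freq_weight * Mod(Y)^2)
  grad <- 2 * prior$lambda *
    Re(fft(prior$freq_weight * Y, inverse = TRUE)) / sqrt(npx)
  list(value = value, gradient = grad)
}

#' Fourier-diagonal Gaussian prior proximal operator
#'
#' Closed-form minimizer of `lambda * sum_k w_k |a_k(z)|^2 + (rho/2) ||z - x||^2`
#' for a covariance specification diagonal in the Fourier domain:
#' per-frequency shrinkage `a_k <- a_k * rho / (rho + 2 * lambda * w_k)`.
#' With `w_k = 1/f_k^2` this is the exact proximal map of the 1/F prior.
#'
#' @param x input image (matrix).
#' @param rho quadratic coupling weight (> 0).
#' @param lambda prior weight (>= 0).
#' @param covariance_spec `"one_over_f"` (default) or a matrix of
#'   per-frequency penalty weights `w_k` (0 entries are unpenalized).
#' @return image matrix.
#' @export
gaussian_prior_prox <- function(x, rho, lambda,
                                covariance_spec = "one_over_f") {
  if (!is.numeric(rho) || rho <= 0) stop_invalid("'rho' must be > 0")
  check_scalar(lambda, "lambda", lower = 0)
  w <- if (is.matrix(covariance_spec)) covariance_spec else {
    p <- one_over_f_prior(1, nrow(x), ncol(x))
    p$freq_weight
  }
  Y <- fft(unclass(x))
  shrink <- rho / (rho + 2 * lambda * w)
  Re(fft(Y * shrink, inverse = TRUE)) / length(x)
}

#' Train the stand-in denoiser prior
#'
#' The full-scale system uses a deep CNN denoiser trained on natural
#' photographs; at desk scale the implicit prior is a *learned spectral
#' Wiener denoiser*: the radially averaged signal power spectrum `S(f)` of
#' the training corpus is estimated by MSE over >= 200 texture images, and
#' denoising applies per-frequency gains `S(f) / (S(f) + sigma^2)` (the
#' MSE-optimal linear filter for stationary Gaussian signals), conditioned on
#' the reported noise standard deviation. The binary valid-region mask input
#' is honoured by mean-filling invalid pixels before filtering. Training is
#' deterministic given the corpus and seed.
#'
#' @param corpus list of images (matrices or [ret_image]s), >= 200.
#' @param noise_stddev_range length-2 positive range the denoiser should
#'   cover (recorded as metadata; the Wiener gains interpolate any sigma).
#' @param seed integer seed (recorded; estimation itself is deterministic).
#' @return object of class `denoiser_prior` with a `$denoise(noisy, sigma,
#'   mask)` function.
#' @export
train_stand_in_denoiser <- function(corpus, noise_stddev_range = c(0.01, 0.5),
                                    seed = 1) {
  if (length(corpus) < 200) {
    stop_invalid("denoiser training corpus too small (%d < 200 images)",
                 length(corpus))
  }
  if (any(noise_stddev_range <= 0)) {
    stop_invalid("noise_stddev_range must be positive")
  }
  h <- nrow(corpus[[1]]); w <- ncol(corpus[[1]])
  npx <- h * w
  # mean signal power per frequency (unitary FFT, mean-removed images)
  S <- matrix(0, h, w)
  for (img in corpus) {
    m <- unclass(img) - mean(img)
    S <- S + Mod(fft(m) / sqrt(npx))^2
  }
  S <- S / length(corpus)
  structure(list(signal_power = S, height = h, width = w,
                 noise_stddev_range = noise_stddev_range, seed = seed,
                 version = "wiener-1"),
            class = c("denoiser_prior", "image_prior"))
}

#' Apply the stand-in denoiser
#'
#' @param prior a trained `denoiser_prior`.
#' @param noisy noisy image matrix.
#' @param noise_stddev reported noise standard deviation (>= 0).
#' @param mask optional binary valid-region matrix; invalid pixels are filled
#'   with the valid mean before filtering and restored afterwards.
#' @return denoised image, clipped to `[-0.1, 1.1]`.
#' @export
denoise_image <- function(prior, noisy, noise_stddev, mask = NULL) {
  stopifnot(inherits(prior, "denoiser_prior"))
  check_scalar(noise_stddev, "noise_stddev", lower = 0)
  x <- unclass(noisy)
  filled <- x
  if (!is.null(mask)) {
    mvalid <- mean(x[mask > 0])
    filled[mask == 0] <- mvalid
  }
  mu <- mean(filled)
  # per-pixel noise power under unitary FFT is sigma^2 at every frequency
  gain <- prior$signal_power / (prior$signal_power + noise_stddev^2)
  gain[1, 1] <- 1  # pass the mean through untouched
  den <- Re(fft(fft(filled - mu) * gain, inverse = TRUE)) / length(x) + mu
  if (!is.null(mask)) den[mask == 0] <- x[mask == 0]
  pmin(pmax(den, -0.1), 1.1)
}

#' Log-spaced rho schedule for the splitting loop
#'
#' @param rho_start,rho_end endpoints (`0 < rho_start < rho_end`).
#' @param K iterations (>= 1).
#' @return numeric vector of length `K`, strictly increasing.
#' @export
rho_schedule <- function(rho_start = 0.1, rho_end = 10, K = 10) {
  if (K < 1) stop_invalid("'K' must be >= 1")
  if (rho_start <= 0 || rho_end <= rho_start) {
    stop_invalid("need 0 < rho_start < rho_end")
  }
  exp(seq(log(rho_start), log(rho_end), length.out = K))
}

#' One prior sub-problem step of the splitting loop
#'
#' For exact Gaussian-family priors this is the closed-form proximal map; for
#' the denoiser prior it is a single denoiser call at noise standard
#' deviation `sqrt(lambda / rho)` (the prior sub-problem is Gaussian
#' denoising at noise variance `lambda / rho`).
#'
#' @param prior an `image_prior` (1/F, Gaussian spec, or denoiser).
#' @param x current image iterate.
#' @param rho coupling weight (> 0).
#' @param lambda prior weight.
#' @param mask optional valid-region mask forwarded to the denoiser.
#' @return updated image matrix.
#' @export
prior_step <- function(prior, x, rho, lambda = 1, mask = NULL) {
  if (rho <= 0) stop_invalid("'rho' must be > 0")
  if (inherits(prior, "one_over_f_prior")) {
    gaussian_prior_prox(x, rho, lambda * prior$lambda, prior$freq_weight)
  } else if (inherits(prior, "denoiser_prior")) {
    denoise_image(prior, x, sqrt(lambda / rho), mask)
  } else if (is.matrix(prior)) {  # raw per-frequency weight matrix
    gaussian_prior_prox(x, rho, lambda, prior)
  } else {
    stop("prior provides neither a proximal map nor a denoiser", call. = FALSE)
  }
}
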