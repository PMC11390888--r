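## Synthetic stimuli: 1/F texture images, Brownian drift trajectories, and
## rendered flashed / jittered movies with the experiment's timing conventions
## (120 Hz display, 1 ms spike bins).

DEFAULT_PIXEL_PITCH_UM <- 11     # microns per display pixel on the retina
DEFAULT_FRAME_PERIOD_MS <- 25 / 3  # 120 Hz
BACKGROUND_GRAY <- 0.5

#' Grayscale stimulus image
#'
#' A luminance image in `[0, 1]` together with its pixel pitch on the retina
#' (microns per pixel). Stands in for the natural photographs used in the
#' experiments.
#'
#' @param pixels numeric matrix with values in `[0, 1]`, both dims >= 16.
#' @param pixel_pitch_um microns per pixel (default 11).
#' @return object of class `ret_image` (a matrix with attributes).
#' @export
ret_image <- function(pixels, pixel_pitch_um = DEFAULT_PIXEL_PITCH_UM) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_invalid("'pixels' must be a numeric matrix")
  }
  if (nrow(pixels) < 16 || ncol(pixels) < 16) {
    stop_invalid("image dimensions must be >= 16, got %d x %d",
                 nrow(pixels), ncol(pixels))
  }
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 1)) {
    stop_invalid("image values must be finite and within [0, 1]")
  }
  check_scalar(pixel_pitch_um, "pixel_pitch_um", lower = 0, allow_zero = FALSE)
  structure(pixels, pixel_pitch_um = pixel_pitch_um,
            class = c("ret_image", "matrix", "array"))
}

#' @export
print.ret_image <- function(x, ...) {
  cat(sprintf("<ret_image> %d x %d px, %.3g um/px, range [%.3f, %.3f]\n",
              nrow(x), ncol(x), attr(x, "pixel_pitch_um"), min(x), max(x)))
  invisible(x)
}

#' Generate a random texture image with a 1/f^alpha power spectrum
#'
#' Natural images have approximately 1/f^2 radial power spectra; these
#' textures stand in for natural photographs in all synthetic experiments.
#' White Gaussian noise is shaped in the Fourier domain by `1/f^(alpha/2)`
#' amplitude weights (radial frequency in cycles/image), inverse-transformed,
#' and affinely rescaled to `[0, 1]`.
#'
#' @param seed integer RNG seed; the same seed gives a bit-identical image.
#' @param height,width image dimensions in pixels (>= 16).
#' @param spectral_exponent alpha >= 0; 0 gives white noise, 2 approximates
#'   natural image statistics (the default).
#' @param pixel_pitch_um microns per pixel.
#' @return a [ret_image].
#' @export
generate_texture_image <- function(seed, height = 64, width = 64,
                                   spectral_exponent = 2,
                                   pixel_pitch_um = DEFAULT_PIXEL_PITCH_UM) {
  if (height < 16 || width < 16) {
    stop_invalid("height and width must be >= 16")
  }
  check_scalar(spectral_exponent, "spectral_exponent", lower = 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  noise <- matrix(rnorm(height * width), height, width)
  f <- radial_frequency_grid(height, width)   # cycles/image
  amp <- 1 / pmax(f, .Machine$double.eps)^(spectral_exponent / 2)
  amp[1, 1] <- 0  # no DC from the noise; mean set by rescaling
  shaped <- Re(fft(fft(noise) * amp, inverse = TRUE)) / (height * width)
  rng <- range(shaped)
  if (rng[2] > rng[1]) {
    shaped <- (shaped - rng[1]) / (rng[2] - rng[1])
  } else {
    shaped[] <- BACKGROUND_GRAY
  }
  ret_image(shaped, pixel_pitch_um)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) return(invisible(NULL))
  assign(".Random.seed", old, envir = globalenv())
}

#' Radial spatial-frequency grid in cycles/image
#'
#' Isotropic radial frequency `f = sqrt(fx^2 + fy^2)` for an `h x w` FFT grid,
#' with `fx, fy` in cycles per image (integer wavenumbers up to Nyquist).
#'
#' @param h,w grid dimensions.
#' @return `h x w` matrix; entry `[1, 1]` (DC) is 0.
#' @export
radial_frequency_grid <- function(h, w) {
  fy <- c(0:floor(h / 2), -((ceiling(h / 2) - 1):1))
  fx <- c(0:floor(w / 2), -((ceiling(w / 2) - 1):1))
  sqrt(outer(fy^2, fx^2, `+`))
}

#' Simulate a fixational-drift eye trajectory
#'
#' Discretized 2D Brownian motion. Per-frame displacement increments are
#' i.i.d. 2D Gaussian with per-axis variance `2 * D` (the eye-movement
#' convention `MSD = <|w_t|^2> = 4 D t`; set `convention = "per_axis"` for
#' per-axis variance `D`). The cumulative micron path is discretized by
#' rounding the *position* (not the increments) to the nearest pixel, ties
#' toward zero, so rounding error does not accumulate.
#'
#' @param n_frames number of display frames (>= 1); frame 1 is at the origin.
#' @param diffusion_um2_per_frame diffusion constant D in um^2/frame
#'   (default 10, the experimental value).
#' @param pixel_pitch_um microns per pixel.
#' @param seed optional integer seed.
#' @param frame_period_ms frame duration in ms.
#' @param convention `"msd4dt"` (default, per-axis increment variance 2D) or
#'   `"per_axis"` (per-axis increment variance D).
#' @return object of class `eye_trajectory`: list with `displacements_um`
#'   (`n_frames x 2`), `displacements_px` (integer `n_frames x 2`),
#'   `frame_period_ms`, `pixel_pitch_um`.
#' @export
simulate_drift_trajectory <- function(n_frames,
                                      diffusion_um2_per_frame = 10,
                                      pixel_pitch_um = DEFAULT_PIXEL_PITCH_UM,
                                      seed = NULL,
                                      frame_period_ms = DEFAULT_FRAME_PERIOD_MS,
                                      convention = c("msd4dt", "per_axis")) {
  if (n_frames < 1) stop_invalid("'n_frames' must be >= 1")
  check_scalar(diffusion_um2_per_frame, "diffusion_um2_per_frame", lower = 0)
  convention <- match.arg(convention)
  if (!is.null(seed)) set.seed(as.integer(seed))
  step_var <- switch(convention,
                     msd4dt = 2 * diffusion_um2_per_frame,
                     per_axis = diffusion_um2_per_frame)
  inc <- matrix(rnorm(2 * (n_frames - 1), sd = sqrt(step_var)),
                ncol = 2)
  um <- rbind(c(0, 0), apply(inc, 2, cumsum))
  if (n_frames == 1) um <- matrix(0, 1, 2)
  px <- round_half_toward_zero(um / pixel_pitch_um)
  structure(list(displacements_um = um,
                 displacements_px = px,
                 frame_period_ms = frame_period_ms,
                 pixel_pitch_um = pixel_pitch_um),
            class = "eye_trajectory")
}

#' Zero (no-movement) trajectory
#' @param n_frames number of frames.
#' @param pixel_pitch_um microns per pixel.
#' @param frame_period_ms frame duration in ms.
#' @return an `eye_trajectory` fixed at the origin.
#' @export
zero_trajectory <- function(n_frames,
                            pixel_pitch_um = DEFAULT_PIXEL_PITCH_UM,
                            frame_period_ms = DEFAULT_FRAME_PERIOD_MS) {
  structure(list(displacements_um = matrix(0, n_frames, 2),
                 displacements_px = matrix(0, n_frames, 2),
                 frame_period_ms = frame_period_ms,
                 pixel_pitch_um = pixel_pitch_um),
            class = "eye_trajectory")
}

#' @export
print.eye_trajectory <- function(x, ...) {
  cat(sprintf("<eye_trajectory> %d frames @ %.3f ms, final offset (%.1f, %.1f) um\n",
              nrow(x$displacements_um), x$frame_period_ms,
              x$displacements_um[nrow(x$displacements_um), 1],
              x$displacements_um[nrow(x$displacements_um), 2]))
  invisible(x)
}

#' Translate an image by an integer pixel offset
#'
#' Regions exposed by the shift are filled with the background gray level.
#' Offset `(dy, dx)` moves image content down/right by `(dy, dx)` pixels
#' (i.e. the output at `(r, c)` is the input at `(r - dy, c - dx)`).
#'
#' @param pixels numeric matrix.
#' @param offset length-2 integer vector `(dy, dx)`.
#' @param background fill value for exposed borders.
#' @return shifted matrix of the same size.
#' @export
shift_image <- function(pixels, offset, background = BACKGROUND_GRAY) {
  dy <- as.integer(offset[1]); dx <- as.integer(offset[2])
  h <- nrow(pixels); w <- ncol(pixels)
  if (abs(dy) >= h || abs(dx) >= w) {
    stop_invalid("shift (%d, %d) exceeds image extent %d x %d", dy, dx, h, w)
  }
  out <- matrix(background, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- pixels[src_r[ok_r], src_c[ok_c]]
  out
}

stim_movie <- function(frames, frame_period_ms, pixel_pitch_um,
                       background = BACKGROUND_GRAY) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  structure(list(frames = frames,  # h x w x t
                 frame_period_ms = frame_period_ms,
                 pixel_pitch_um = pixel_pitch_um,
                 background = background),
            class = "stim_movie")
}

#' @export
print.stim_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<stim_movie> %d frames of %d x %d px @ %.3f ms (%.0f ms total)\n",
              d[3], d[1], d[2], x$frame_period_ms, d[3] * x$frame_period_ms))
  invisible(x)
}

#' Render a flashed-image trial
#'
#' The image is shown for `flash_ms` and followed by `gray_ms` of uniform
#' background (the experimental flash protocol is 100 ms image + 400 ms gray
#' at 120 Hz, i.e. 12 + 48 frames).
#'
#' @param image a [ret_image].
#' @param flash_ms,gray_ms durations in ms; must be positive multiples of the
#'   frame period (gray_ms may be 0).
#' @param frame_period_ms display frame duration.
#' @return a `stim_movie` whose frames are the image then background.
#' @export
render_flashed_trial <- function(image, flash_ms = 100, gray_ms = 400,
                                 frame_period_ms = DEFAULT_FRAME_PERIOD_MS) {
  n_flash <- flash_ms / frame_period_ms
  n_gray <- gray_ms / frame_period_ms
  if (flash_ms <= 0 || abs(n_flash - round(n_flash)) > 1e-9 ||
      gray_ms < 0 || abs(n_gray - round(n_gray)) > 1e-9) {
    stop_invalid("flash_ms and gray_ms must be nonnegative multiples of the frame period (%.4f ms)",
                 frame_period_ms)
  }
  n_flash <- as.integer(round(n_flash)); n_gray <- as.integer(round(n_gray))
  h <- nrow(image); w <- ncol(image)
  frames <- array(BACKGROUND_GRAY, c(h, w, n_flash + n_gray))
  frames[, , seq_len(n_flash)] <- unclass(image)
  stim_movie(frames, frame_period_ms, attr(image, "pixel_pitch_um"))
}

#' Render a jittered (fixational drift) trial
#'
#' Frame `t` is the image translated by the trajectory's integer pixel offset
#' at frame `t`; borders exposed by the shift are filled with background gray.
#'
#' @param image a [ret_image].
#' @param trajectory an `eye_trajectory`; its length sets the frame count.
#' @return a `stim_movie`.
#' @export
render_jittered_trial <- function(image, trajectory) {
  stopifnot(inherits(trajectory, "eye_trajectory"))
  px <- trajectory$displacements_px
  h <- nrow(image); w <- ncol(image)
  frames <- array(BACKGROUND_GRAY, c(h, w, nrow(px)))
  for (t in seq_len(nrow(px))) {
    frames[, , t] <- shift_image(unclass(image), px[t, ])
  }
  stim_movie(frames, trajectory$frame_period_ms,
             attr(image, "pixel_pitch_um"))
}

#' Collections of flashed / jittered trials
#'
#' Lightweight containers used by the simulator and fitter: they carry the
#' per-trial images (and trajectories) plus timing, without materializing the
#' full pixel movie of every trial.
#'
#' @param images list of [ret_image]s, one per trial.
#' @param flash_ms,gray_ms flash protocol timing in ms.
#' @param frame_period_ms display frame duration in ms.
#' @return object of class `flashed_stimulus_set`.
#' @export
flashed_stimulus_set <- function(images, flash_ms = 100, gray_ms = 400,
                                 frame_period_ms = DEFAULT_FRAME_PERIOD_MS) {
  stopifnot(length(images) >= 1)
  n_frames <- as.integer(round((flash_ms + gray_ms) / frame_period_ms))
  structure(list(images = images, flash_ms = flash_ms, gray_ms = gray_ms,
                 frame_period_ms = frame_period_ms,
                 n_frames_per_trial = n_frames,
                 flash_frames = seq_len(as.integer(round(flash_ms / frame_period_ms)))),
            class = "flashed_stimulus_set")
}

#' @param trajectories list of `eye_trajectory`, one per trial (same length).
#' @rdname flashed_stimulus_set
#' @export
drift_stimulus_set <- function(images, trajectories,
                               frame_period_ms = DEFAULT_FRAME_PERIOD_MS) {
  stopifnot(length(images) == length(trajectories))
  n_frames <- nrow(trajectories[[1]]$displacements_px)
  structure(list(images = images, trajectories = trajectories,
                 frame_period_ms = frame_period_ms,
                 n_frames_per_trial = n_frames),
            class = "drift_stimulus_set")
}
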