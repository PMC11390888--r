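#' Numerically stable sigmoid and log(1 + exp(x))
#'
#' The Bernoulli spiking nonlinearity is `exp(x) / (1 + exp(x))`; its
#' log-partition `log(1 + exp(x))` appears in every encoding likelihood.
#' Both are computed in a branchless form that is exact for large `|x|`.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
sigmoid <- function(x) {
  # plogis is the stable logistic CDF
  stats::plogis(x)
}

#' @rdname sigmoid
#' @export
log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Round half toward zero
#'
#' Used when discretizing micron-scale eye positions to integer pixels: ties
#' are broken toward zero so that a displacement of exactly half a pixel does
#' not move the image.
#'
#' @param x numeric vector.
#' @return numeric vector of integers (as doubles).
#' @keywords internal
round_half_toward_zero <- function(x) {
  sign(x) * ceiling(abs(x) - 0.5)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("'%s' must be a finite numeric scalar", name)
  }
  if (x < lower || (!allow_zero && x == lower)) {
    stop_invalid("'%s' must be %s %s", name,
                 if (allow_zero) ">=" else ">", format(lower))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map 1 ms bins to display frames
#'
#' Display frames last `frame_period_ms` (8.33 ms at 120 Hz) while spikes are
#' binned at 1 ms, so frame boundaries do not fall on integer bins. Bin `t`
#' (1-based) is assigned to the frame on screen during that millisecond:
#' `floor((t - 1) / frame_period_ms) + 1`.
#'
#' @param n_bins number of 1 ms bins.
#' @param frame_period_ms frame duration in ms.
#' @return integer vector of frame indices, length `n_bins`.
#' @export
frame_of_bin <- function(n_bins, frame_period_ms) {
  as.integer(floor((seq_len(n_bins) - 1) / frame_period_ms)) + 1L
}

#' Number of 1 ms bins spanned by `n_frames` display frames
#' @param n_frames frame count.
#' @param frame_period_ms frame duration in ms.
#' @return integer bin count.
#' @export
bins_for_frames <- function(n_frames, frame_period_ms) {
  as.integer(round(n_frames * frame_period_ms))
}
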