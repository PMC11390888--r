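## Temporal raised-cosine bases and spatial tensor B-spline bases used to
## parameterize LNBRC filters.

#' Log-time raised-cosine basis
#'
#' Standard GLM temporal basis: half-overlapping raised-cosine bumps in
#' warped time `phi(t) = log(t + log_stretch)`, evaluated at integer 1 ms
#' lags `1..t_max_ms`. Within the interior of the span the bumps form a
#' partition of unity. All support is at lags >= 1 ms (strictly causal).
#'
#' @param n_funcs number of basis functions (>= 1).
#' @param t_min_ms,t_max_ms span of the bump centers in ms (1 <= t_min < t_max).
#' @param log_stretch warp constant in ms (larger = more linear spacing).
#' @return `t_max_ms x n_funcs` matrix; row `t` is the basis at lag `t` ms.
#'   Attributes record the construction parameters.
#' @export
raised_cosine_basis <- function(n_funcs, t_min_ms, t_max_ms, log_stretch = 10) {
  if (n_funcs < 1) stop_invalid("'n_funcs' must be >= 1")
  if (!(t_min_ms >= 1 && t_min_ms < t_max_ms)) {
    stop_invalid("need 1 <= t_min_ms < t_max_ms, got [%s, %s]",
                 format(t_min_ms), format(t_max_ms))
  }
  phi <- function(t) log(t + log_stretch)
  lo <- phi(t_min_ms); hi <- phi(t_max_ms)
  if (n_funcs == 1) {
    # snap the single center to an integer lag so the bump peaks at exactly 1
    centers <- phi(round(exp((lo + hi) / 2) - log_stretch))
    delta <- (hi - lo) / 2
  } else {
    centers <- seq(lo, hi, length.out = n_funcs)
    delta <- centers[2] - centers[1]
  }
  lags <- seq_len(t_max_ms)
  x <- outer(phi(lags), centers, `-`) / delta  # lags x n_funcs
  B <- 0.5 * (1 + cos(pi * pmin(pmax(x, -1), 1)))
  B[abs(x) >= 1] <- 0
  structure(B, lags_ms = lags, centers_phi = centers, delta = delta,
            log_stretch = log_stretch, t_min_ms = t_min_ms,
            class = c("raised_cosine_basis", "matrix", "array"))
}

#' Interior lag range over which the raised-cosine basis sums to 1
#' @param basis a [raised_cosine_basis].
#' @return length-2 vector of ms lags (first/last center), or NULL if n = 1.
#' @export
rc_basis_interior <- function(basis) {
  ctr <- attr(basis, "centers_phi")
  if (length(ctr) < 2) return(NULL)
  ls <- attr(basis, "log_stretch")
  c(ceiling(exp(ctr[1]) - ls), floor(exp(ctr[length(ctr)]) - ls))
}

#' Tensor-product cubic B-spline spatial basis over a crop window
#'
#' The spatial factor of each stimulus filter is represented on a rectangular
#' crop around the cell's receptive field with a fixed number of cubic
#' B-spline functions per dimension (knot spacing adapts to the crop size).
#'
#' @param crop_rows,crop_cols integer vectors of image rows/cols in the crop.
#' @param n_per_dim basis functions per dimension (default 8).
#' @return list with `B` (`npx x (n_per_dim^2)` matrix mapping coefficients to
#'   pixels of the crop, pixels in column-major crop order), `crop_rows`,
#'   `crop_cols`.
#' @export
spline_spatial_basis <- function(crop_rows, crop_cols, n_per_dim = 8) {
  By <- bspline_1d(length(crop_rows), n_per_dim)
  Bx <- bspline_1d(length(crop_cols), n_per_dim)
  # tensor product: pixel (r, c) -> kron row
  B <- matrix(0, length(crop_rows) * length(crop_cols), ncol(By) * ncol(Bx))
  for (j in seq_len(ncol(Bx))) {
    cols <- (j - 1) * ncol(By) + seq_len(ncol(By))
    B[, cols] <- kronecker(Bx[, j, drop = FALSE], By)
  }
  list(B = B, crop_rows = crop_rows, crop_cols = crop_cols,
       n_per_dim = n_per_dim)
}

bspline_1d <- function(n_px, n_funcs) {
  if (n_px < 4 || n_funcs < 4) {
    # tiny crops: fall back to an identity-ish basis
    return(diag(n_px)[, seq_len(min(n_px, max(n_funcs, 1))), drop = FALSE])
  }
  x <- seq_len(n_px)
  n_inner <- max(n_funcs - 4, 0)
  knots <- if (n_inner > 0) {
    seq(1, n_px, length.out = n_inner + 2)[-c(1, n_inner + 2)]
  } else NULL
  splines::bs(x, knots = knots, degree = 3, intercept = TRUE)[, , drop = FALSE]
}
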