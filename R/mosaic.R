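## RGC mosaics: jittered hexagonal lattices of the four dominant cell types,
## with receptive-field radii set so neighbouring fields abut (spacing is
## approximately twice the RF radius).

RGC_TYPES <- c("ON_parasol", "OFF_parasol", "ON_midget", "OFF_midget")

#' Default mosaic spacings (um) for peripheral macaque retina
#'
#' Midget spacing ~70 um (median midget RF radius ~35 um, spacing about twice
#' the radius); parasol spacing about twice the midget spacing.
#' @return named numeric vector of lattice spacings per cell type.
#' @export
default_mosaic_spacings <- function() {
  c(ON_parasol = 140, OFF_parasol = 140, ON_midget = 70, OFF_midget = 70)
}

#' Build a synthetic RGC mosaic
#'
#' Each cell type is laid out on an independent jittered hexagonal lattice
#' clipped to the field, with a random lattice offset and orientation so that
#' the four mosaics are not in register. The RF radius is `spacing / 2`
#' (neighbouring receptive fields abut).
#'
#' @param field_size_um length-2 vector `(height, width)` of the field in um
#'   (a scalar is recycled).
#' @param spacings_um named vector of lattice spacings per type (subset of
#'   [RGC_TYPES]); defaults to [default_mosaic_spacings()].
#' @param jitter_fraction positional jitter sd as a fraction of spacing,
#'   in `[0, 1)`.
#' @param seed optional integer seed.
#' @return object of class `rgc_mosaic`: a data.frame with columns `cell_id`,
#'   `cell_type`, `x_um`, `y_um`, `radius_um` and attribute `field_size_um`.
#' @export
build_mosaic <- function(field_size_um,
                         spacings_um = default_mosaic_spacings(),
                         jitter_fraction = 0.12,
                         seed = NULL) {
  if (length(field_size_um) == 1) field_size_um <- rep(field_size_um, 2)
  if (any(field_size_um <= 0)) stop_invalid("'field_size_um' must be positive")
  if (jitter_fraction < 0 || jitter_fraction >= 1) {
    stop_invalid("'jitter_fraction' must be in [0, 1)")
  }
  if (is.null(names(spacings_um)) || !all(names(spacings_um) %in% RGC_TYPES)) {
    stop_invalid("'spacings_um' must be named with RGC types (%s)",
                 paste(RGC_TYPES, collapse = ", "))
  }
  if (any(spacings_um <= 0)) stop_invalid("spacings must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  rows <- list()
  for (ty in names(spacings_um)) {
    a <- spacings_um[[ty]]
    if (any(field_size_um < a)) {
      stop_invalid("field %g x %g um too small for one %s cell (spacing %g um)",
                   field_size_um[1], field_size_um[2], ty, a)
    }
    pts <- hex_lattice(field_size_um, a,
                       offset = if (jitter_fraction > 0) runif(2, 0, a) else c(0, 0))
    if (jitter_fraction > 0) {
      pts <- pts + matrix(rnorm(length(pts), sd = jitter_fraction * a),
                          ncol = 2)
      pts[, 1] <- pmin(pmax(pts[, 1], 0), field_size_um[1])
      pts[, 2] <- pmin(pmax(pts[, 2], 0), field_size_um[2])
    }
    rows[[ty]] <- data.frame(cell_type = ty, y_um = pts[, 1], x_um = pts[, 2],
                             radius_um = a / 2)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df <- cbind(cell_id = seq_len(nrow(df)), df)
  structure(df, field_size_um = field_size_um,
            class = c("rgc_mosaic", "data.frame"))
}

# hexagonal lattice points (y, x) covering a (h, w) field with spacing a
hex_lattice <- function(field, a, offset = c(0, 0)) {
  row_h <- a * sqrt(3) / 2
  ys <- seq(offset[1] %% row_h, field[1], by = row_h)
  pts <- list()
  for (i in seq_along(ys)) {
    x0 <- (offset[2] + if (i %% 2 == 0) a / 2 else 0) %% a
    xs <- seq(x0, field[2], by = a)
    pts[[i]] <- cbind(ys[i], xs)
  }
  do.call(rbind, pts)
}

#' @export
print.rgc_mosaic <- function(x, ...) {
  tab <- table(x$cell_type)
  cat(sprintf("<rgc_mosaic> %d cells over %g x %g um (%s)\n", nrow(x),
              attr(x, "field_size_um")[1], attr(x, "field_size_um")[2],
              paste(names(tab), tab, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Median nearest-neighbour distance within one cell type
#' @param mosaic an `rgc_mosaic`.
#' @param cell_type one of [RGC_TYPES].
#' @return scalar distance in um (NA for singleton types).
#' @export
median_nn_distance <- function(mosaic, cell_type) {
  pts <- mosaic[mosaic$cell_type == cell_type, c("y_um", "x_um")]
  if (nrow(pts) < 2) return(NA_real_)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  median(apply(d, 1, min))
}

#' Coupled-neighbour selection rule
#'
#' Cell `j` (of any type) is coupled to cell `i` when their receptive-field
#' centers are within a multiple of the median nearest-neighbour distance of
#' cell `i`'s type: factor 2 for parasol cells, 2.5 for midget cells.
#'
#' @param mosaic an `rgc_mosaic`.
#' @param cell `cell_id` of the target cell.
#' @param factors named multipliers per type class.
#' @return integer vector of neighbour `cell_id`s (never includes `cell`).
#' @export
select_coupled_neighbors <- function(mosaic, cell,
                                     factors = c(parasol = 2, midget = 2.5)) {
  i <- match(cell, mosaic$cell_id)
  if (is.na(i)) stop_invalid("cell %s not in mosaic", format(cell))
  ty <- mosaic$cell_type[i]
  klass <- if (grepl("parasol", ty)) "parasol" else "midget"
  nn <- median_nn_distance(mosaic, ty)
  if (is.na(nn)) {
    warning(sprintf("cell type %s has a single cell; no neighbour rule, empty set", ty))
    return(integer(0))
  }
  thr <- factors[[klass]] * nn
  d <- sqrt((mosaic$y_um - mosaic$y_um[i])^2 + (mosaic$x_um - mosaic$x_um[i])^2)
  mosaic$cell_id[d <= thr & mosaic$cell_id != cell]
}

#' Write / read a mosaic as CSV
#' @param mosaic an `rgc_mosaic`.
#' @param path file path.
#' @return `read_mosaic_csv` returns an `rgc_mosaic`.
#' @export
write_mosaic_csv <- function(mosaic, path) {
  df <- as.data.frame(mosaic)
  attr(df, "field_size_um") <- NULL
  write.csv(cbind(df,
                  field_h_um = attr(mosaic, "field_size_um")[1],
                  field_w_um = attr(mosaic, "field_size_um")[2]),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mosaic_csv
#' @export
read_mosaic_csv <- function(path) {
  df <- read.csv(path)
  field <- c(df$field_h_um[1], df$field_w_um[1])
  df <- df[, c("cell_id", "cell_type", "y_um", "x_um", "radius_um")]
  structure(df, field_size_um = field,
            class = c("rgc_mosaic", "data.frame"))
}
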