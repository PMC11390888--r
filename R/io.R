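## Plain-text serialization: images and movies as CSV, spike trains as sparse
## event tables, encoders and configs as JSON, PNG previews for images.

#' Write / read an image as CSV
#' @param image a [ret_image] or matrix.
#' @param path file path.
#' @return `read_image_csv` returns a [ret_image].
#' @export
write_image_csv <- function(image, path) {
  utils::write.table(unclass(image), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @param pixel_pitch_um pitch to attach on read.
#' @rdname write_image_csv
#' @export
read_image_csv <- function(path, pixel_pitch_um = DEFAULT_PIXEL_PITCH_UM) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  ret_image(m, pixel_pitch_um)
}

#' PNG preview of an image
#' @param image matrix in [0, 1].
#' @param path output path.
#' @export
write_image_png <- function(image, path) {
  grDevices::png(path, width = ncol(image) * 4, height = nrow(image) * 4)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(unclass(image))[, nrow(image):1], col = gray(seq(0, 1, 0.01)),
                  axes = FALSE, useRaster = TRUE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Write / read spike trains as a sparse event table (CSV)
#' @param spikes a `spike_trains` matrix.
#' @param path file path.
#' @export
write_spikes_csv <- function(spikes, path) {
  ev <- spikes_to_events(spikes)
  write.csv(ev, path, row.names = FALSE)
  cat(sprintf("# cells=%s n_bins=%d\n",
              paste(attr(spikes, "cell_ids"), collapse = ";"), ncol(spikes)),
      file = paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  meta <- readLines(paste0(path, ".meta"), n = 1)
  ids <- as.integer(strsplit(sub(".*cells=([0-9;]+).*", "\\1", meta), ";")[[1]])
  n_bins <- as.integer(sub(".*n_bins=([0-9]+).*", "\\1", meta))
  ev <- read.csv(path)
  events_to_spikes(ev, ids, n_bins)
}

#' Serialize a fitted or ground-truth encoder to JSON
#'
#' Stores per-cell filter weights with their basis descriptors so that
#' kernels are reconstructable in ms / pixel units.
#'
#' @param encoder an `rgc_encoder`.
#' @param path output path.
#' @export
write_encoder_json <- function(encoder, path) {
  bs <- encoder$basis_set
  payload <- list(
    geometry = encoder$geometry[c("height", "width", "pixel_pitch_um")],
    basis = list(
      temporal = list(n = ncol(bs$temporal), t_max = nrow(bs$temporal),
                      log_stretch = attr(bs$temporal, "log_stretch"),
                      t_min = attr(bs$temporal, "t_min_ms")),
      feedback = list(n = ncol(bs$feedback), t_max = nrow(bs$feedback),
                      log_stretch = attr(bs$feedback, "log_stretch"),
                      t_min = attr(bs$feedback, "t_min_ms")),
      coupling = list(n = ncol(bs$coupling), t_max = nrow(bs$coupling),
                      log_stretch = attr(bs$coupling, "log_stretch"),
                      t_min = attr(bs$coupling, "t_min_ms")),
      spatial_n = bs$spatial_n),
    cells = lapply(encoder$cells, function(cl) {
      list(cell_id = cl$cell_id, cell_type = cl$cell_type,
           crop_rows = range(cl$crop_rows), crop_cols = range(cl$crop_cols),
           spatial = as.numeric(cl$spatial),
           temporal_weights = cl$temporal_weights,
           feedback_weights = cl$feedback_weights,
           coupling_weights = if (is.null(cl$coupling_weights)) NULL else
             as.numeric(cl$coupling_weights),
           neighbors = cl$neighbors, bias = cl$bias)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param mosaic the matching `rgc_mosaic` (for cell types / coupling rule).
#' @rdname write_encoder_json
#' @export
read_encoder_json <- function(path, mosaic) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  bs <- list(
    temporal = raised_cosine_basis(p$basis$temporal$n, p$basis$temporal$t_min,
                                   p$basis$temporal$t_max,
                                   p$basis$temporal$log_stretch),
    feedback = raised_cosine_basis(p$basis$feedback$n, p$basis$feedback$t_min,
                                   p$basis$feedback$t_max,
                                   p$basis$feedback$log_stretch),
    coupling = raised_cosine_basis(p$basis$coupling$n, p$basis$coupling$t_min,
                                   p$basis$coupling$t_max,
                                   p$basis$coupling$log_stretch),
    spatial_n = p$basis$spatial_n)
  cells <- lapply(seq_len(nrow(p$cells)), function(i) {
    ci <- p$cells[i, ]
    crop_rows <- ci$crop_rows[[1]][1]:ci$crop_rows[[1]][2]
    crop_cols <- ci$crop_cols[[1]][1]:ci$crop_cols[[1]][2]
    nbr <- ci$neighbors[[1]]
    cw <- ci$coupling_weights[[1]]
    lnbrc_cell(ci$cell_id, ci$cell_type, crop_rows, crop_cols,
               matrix(ci$spatial[[1]], length(crop_rows), length(crop_cols)),
               ci$temporal_weights[[1]], ci$feedback_weights[[1]],
               if (length(nbr)) matrix(cw, ncol = length(nbr)) else NULL,
               if (length(nbr)) nbr else integer(0), ci$bias, bs)
  })
  geom <- encoder_geometry(p$geometry$height, p$geometry$width,
                           p$geometry$pixel_pitch_um)
  structure(list(cells = cells, mosaic = mosaic, geometry = geom,
                 basis_set = bs),
            class = "rgc_encoder")
}
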