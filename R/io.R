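#' Write a wave field as delimited text with a JSON sidecar
#'
#' The canonical on-disk container: `<stem>_real.tsv` and
#' `<stem>_imag.tsv` hold the real and imaginary parts as tab-delimited
#' `nx x ny` matrices (rows = x), and `<stem>.json` carries the metadata
#' needed to interpret them — pixel spacing `h` (meters), `origin`,
#' `frequency_hz` and optional ROI definitions.
#'
#' @param field A [wave_field()].
#' @param stem Path prefix (without extension).
#' @param rois Optional named ROI list stored in the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_wave_field <- function(field, stem, rois = NULL) {
  stopifnot(inherits(field, "wave_field"))
  paths <- paste0(stem, c("_real.tsv", "_imag.tsv", ".json"))
  utils::write.table(Re(field$values), paths[1], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(Im(field$values), paths[2], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(nx = field$grid$nx, ny = field$grid$ny, h = field$grid$h,
               origin = field$grid$origin, frequency_hz = field$frequency_hz)
  if (!is.null(rois)) meta$rois <- rois
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a wave field written by [write_wave_field()]
#'
#' @param stem Path prefix used when writing.
#' @return A [wave_field()]; any ROIs from the sidecar are attached as
#'   the `rois` attribute.
#' @export
read_wave_field <- function(stem) {
  meta_path <- paste0(stem, ".json")
  if (!file.exists(meta_path)) stop("missing sidecar file: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (k in c("h", "frequency_hz", "nx", "ny"))
    if (is.null(meta[[k]])) stop("sidecar is missing required key '", k, "'")
  re <- as.matrix(utils::read.table(paste0(stem, "_real.tsv"), sep = "\t"))
  im <- as.matrix(utils::read.table(paste0(stem, "_imag.tsv"), sep = "\t"))
  dimnames(re) <- dimnames(im) <- NULL
  origin <- if (is.null(meta$origin)) c(0, 0) else as.numeric(meta$origin)
  grid <- mre_grid(meta$nx, meta$ny, meta$h, origin)
  f <- wave_field(re + 1i * im, grid, meta$frequency_hz)
  if (!is.null(meta$rois)) {
    attr(f, "rois") <- lapply(meta$rois, function(r)
      list(xlim = as.numeric(r$xlim), ylim = as.numeric(r$ylim)))
  }
  f
}

#' Read a snapshot stack from a multi-page TIFF
#'
#' Pages are taken as the N uniform phase-offset snapshots in order.
#' TIFF rasters are stored row-major from the top-left, so each page is
#' transposed and flipped to the package's `[x, y]` (y up) convention.
#'
#' @param path Path to the multi-page TIFF.
#' @param h Pixel spacing in meters.
#' @param frequency_hz Vibration frequency in Hz.
#' @param origin Physical coordinate of pixel (0, 0).
#' @return A [snapshot_stack()].
#' @export
read_snapshot_tiff <- function(path, h, frequency_hz, origin = c(0, 0)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("snapshot TIFF must have at least 2 pages")
  snaps <- lapply(pages, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]
    t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  })
  grid <- mre_grid(nrow(snaps[[1]]), ncol(snaps[[1]]), h, origin)
  snapshot_stack(snaps, grid, frequency_hz)
}

#' Write a snapshot stack as a multi-page TIFF
#'
#' All pages are jointly rescaled to the TIFF sample range `[0, 1]`, so
#' the stack is recovered up to one affine map: the constant offset has
#' no first temporal harmonic and drops out in [combine_snapshots()],
#' and the positive scale factor cancels in the wave-vector and
#' attenuation estimators, which are amplitude invariant.
#'
#' @param stack A [snapshot_stack()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snapshot_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "snapshot_stack"))
  lo <- min(vapply(stack$snapshots, min, 0))
  hi <- max(vapply(stack$snapshots, max, 0))
  sc <- if (hi > lo) hi - lo else 1
  pages <- lapply(stack$snapshots, function(m) {
    t((m[, rev(seq_len(ncol(m))), drop = FALSE] - lo) / sc)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' Export a vector-field map as a delimited table
#'
#' @param vmap A `vector_field_map`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_vector_map <- function(vmap, path) {
  stopifnot(inherits(vmap, "vector_field_map"))
  utils::write.table(as.data.frame(vmap), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a moduli map as a delimited table
#'
#' @param mmap A [moduli_map()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_moduli_map <- function(mmap, path) {
  stopifnot(inherits(mmap, "moduli_map"))
  utils::write.table(as.data.frame(mmap), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
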