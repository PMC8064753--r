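#' Single-channel intensity image
#'
#' `image_field()` wraps one 2D grayscale intensity grid together with the
#' acquisition metadata every detector and measurement in the package
#' consumes: the physical pixel size, a channel label, and the bit depth the
#' values are meant to fit. Matrices are indexed `[row, col]`, 1-based, with
#' pixel centers at integer coordinates; this convention is used throughout
#' the package.
#'
#' @param data Numeric matrix of non-negative, finite intensities.
#' @param pixel_size Physical pixel size in micrometers per pixel. The
#'   default (0.043) matches high-resolution Airyscan-type confocal
#'   acquisition of fly brain cell bodies.
#' @param channel Free-text channel label (e.g. `"Me31B-GFP"`).
#' @param bit_depth Either 16 or 32; rendered/stored values are expected to
#'   fit `[0, 2^bit_depth - 1]`.
#' @return An object of class `image_field`.
#' @export
image_field <- function(data, pixel_size = 0.043, channel = "unknown",
                        bit_depth = 16L) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("image data must be finite", call. = FALSE)
  }
  if (any(data < 0)) {
    stop("image data must be non-negative", call. = FALSE)
  }
  .stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(16L, 32L)) {
    stop("`bit_depth` must be 16 or 32", call. = FALSE)
  }
  structure(
    list(data = data, pixel_size = pixel_size, channel = as.character(channel),
         bit_depth = bit_depth),
    class = "image_field"
  )
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("<image_field> %d x %d px, %.4g um/px, channel '%s', %d-bit\n",
              nrow(x$data), ncol(x$data), x$pixel_size, x$channel,
              x$bit_depth))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_field <- function(x) dim(x$data)

#' Crop a rectangular region out of a field
#'
#' @param field An [image_field()].
#' @param region Integer vector `c(row_min, row_max, col_min, col_max)`,
#'   1-based inclusive bounds; must lie inside the field.
#' @return The cropped [image_field()].
#' @export
crop_field <- function(field, region) {
  stopifnot(inherits(field, "image_field"))
  region <- .check_region(region, dim(field$data))
  image_field(field$data[region[1]:region[2], region[3]:region[4],
                         drop = FALSE],
              pixel_size = field$pixel_size, channel = field$channel,
              bit_depth = field$bit_depth)
}

#' Per-pixel maximum-intensity projection of a stack
#'
#' @param frames A list of [image_field()] objects sharing one shape.
#' @return An [image_field()] holding the per-pixel maximum over frames.
#' @export
max_project <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            all(vapply(frames, inherits, logical(1), "image_field")))
  dims <- vapply(frames, function(f) dim(f$data), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same shape", call. = FALSE)
  }
  proj <- Reduce(pmax, lapply(frames, `[[`, "data"))
  image_field(proj, pixel_size = frames[[1]]$pixel_size,
              channel = frames[[1]]$channel,
              bit_depth = frames[[1]]$bit_depth)
}

#' Read / write intensity TIFF files
#'
#' `read_field()` reads a single-page grayscale TIFF as an [image_field()];
#' `read_stack()` reads a multi-page TIFF as a list of fields (one per
#' frame). `write_field()` / `write_stack()` are their inverses. Values are
#' stored at native integer scale (no display rescaling).
#'
#' @param path File path.
#' @param pixel_size,channel,bit_depth Metadata attached to the result (TIFF
#'   tags are not relied upon).
#' @return `read_field()`: an [image_field()]; `read_stack()`: a list of
#'   them.
#' @export
read_field <- function(path, pixel_size = 0.043, channel = "unknown",
                       bit_depth = 16L) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  image_field(m + 0, pixel_size = pixel_size, channel = channel,
              bit_depth = bit_depth)
}

#' @rdname read_field
#' @export
read_stack <- function(path, pixel_size = 0.043, channel = "unknown",
                       bit_depth = 16L) {
  pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  lapply(pages, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]
    image_field(m + 0, pixel_size = pixel_size, channel = channel,
                bit_depth = bit_depth)
  })
}

#' @rdname read_field
#' @param field An [image_field()] to write.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "image_field"))
  scale <- 2^field$bit_depth - 1
  tiff::writeTIFF(field$data / scale, path,
                  bits.per.sample = if (field$bit_depth == 16L) 16L else 32L)
  invisible(path)
}

#' @rdname read_field
#' @param frames A list of [image_field()] objects (one TIFF page each).
#' @export
write_stack <- function(frames, path) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  scale <- 2^frames[[1]]$bit_depth - 1
  tiff::writeTIFF(lapply(frames, function(f) f$data / scale), path,
                  bits.per.sample = if (frames[[1]]$bit_depth == 16L) 16L
                                    else 32L)
  invisible(path)
}
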