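#' Micrograph container
#'
#' A micrograph is a 2D intensity matrix together with its physical pixel
#' size (micrometers per pixel) and bit depth. All segmentation functions in
#' the package take and return this container or plain matrices derived from
#' it.
#'
#' @param intensity numeric matrix of non-negative intensities, row/column
#'   indexed (row 1 is the top of the image).
#' @param pixel_size physical pixel size in micrometers per pixel.
#' @param bit_depth integer, 8 or 16. Intensities must lie within
#'   `[0, 2^bit_depth - 1]`.
#' @param image_id character label used in output records.
#' @return An object of class `micrograph`.
#' @examples
#' img <- micrograph(matrix(100, 8, 8), pixel_size = 0.107)
#' img
#' @export
micrograph <- function(intensity, pixel_size, bit_depth = 16L, image_id = "img") {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("intensity must be a numeric matrix", call. = FALSE)
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  maxv <- 2^bit_depth - 1
  if (any(intensity < 0) || any(intensity > maxv))
    stop(sprintf("intensities must lie in [0, %d]", maxv), call. = FALSE)
  structure(list(intensity = intensity, pixel_size = pixel_size,
                 bit_depth = as.integer(bit_depth), image_id = image_id),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph '%s'> %d x %d px, %d-bit, %.4g um/px\n",
              x$image_id, nrow(x$intensity), ncol(x$intensity),
              x$bit_depth, x$pixel_size))
  cat(sprintf("  intensity range [%.6g, %.6g]\n",
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$intensity)

#' Read a grayscale TIFF micrograph
#'
#' Reads an 8- or 16-bit grayscale TIFF and attaches the pixel-size
#' calibration, which TIFF files do not reliably carry.
#'
#' @param path path to a TIFF file.
#' @param pixel_size micrometers per pixel.
#' @param image_id label; defaults to the file name.
#' @return A [micrograph].
#' @export
read_micrograph <- function(path, pixel_size, image_id = basename(path)) {
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] != 1L)
      stop("only single-channel grayscale TIFF is supported", call. = FALSE)
    raw <- raw[, , 1L]
  }
  bd <- if (max(raw) > 255) 16L else attr(raw, "bits.per.sample")
  if (is.null(bd)) bd <- 16L
  micrograph(raw, pixel_size = pixel_size, bit_depth = as.integer(bd),
             image_id = image_id)
}

#' Write a micrograph as a grayscale TIFF
#'
#' @param img a [micrograph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  maxv <- 2^img$bit_depth - 1
  tiff::writeTIFF(img$intensity / maxv, path,
                  bits.per.sample = img$bit_depth)
  invisible(path)
}
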