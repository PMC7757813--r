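#' Grayscale raster image with physical resolution
#'
#' The carrier object for all pipeline stages: a 2-D matrix of non-negative
#' pixel intensities together with the pixel size in micrometres. Intensities
#' are integer counts on input (8/16-bit cameras) and become real-valued after
#' intensity leveling. Coordinates are 0-based, row-major and pixel-centred;
#' all physical lengths in this package are micrometres.
#'
#' @param pixels numeric matrix of non-negative intensities (rows = y,
#'   columns = x).
#' @param resolution pixel size in micrometres per pixel (scalar > 0).
#' @return An object of class \code{raster_image} with fields \code{pixels}
#'   and \code{resolution}.
#' @examples
#' img <- raster_image(matrix(0, 4, 5), resolution = 0.462)
#' dim(img$pixels)
#' @export
raster_image <- function(pixels, resolution) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix (single channel)")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one pixel")
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      !is.finite(resolution) || resolution <= 0)
    stop("resolution must be a single positive number (um/pixel)")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("pixels must be finite")
  if (min(pixels) < 0)
    stop("pixels must be non-negative")
  structure(list(pixels = pixels, resolution = resolution),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("raster_image: %d x %d px at %.4g um/px (%.1f x %.1f um)\n",
              nrow(x$pixels), ncol(x$pixels), x$resolution,
              nrow(x$pixels) * x$resolution, ncol(x$pixels) * x$resolution))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Convert a physical length to pixels
#'
#' Linear unit conversion used by every micron-denominated filter parameter.
#' No rounding is applied; each filter rounds (and odd-forces, where needed)
#' according to its own contract.
#'
#' @param value_um length in micrometres (>= 0).
#' @param resolution micrometres per pixel (> 0).
#' @return Length in pixels (real-valued).
#' @examples
#' um_to_px(45, 0.462)   # 97.40 px
#' um_to_px(6, 0.368)    # 16.30 px
#' @export
um_to_px <- function(value_um, resolution) {
  if (!is.numeric(resolution) || any(resolution <= 0) || anyNA(resolution))
    stop("resolution must be > 0")
  if (any(value_um < 0)) stop("value_um must be >= 0")
  value_um / resolution
}

#' Read a grayscale micrograph from TIFF or PNG
#'
#' Multi-channel images are reduced by explicit channel selection only; there
#' is no automatic RGB-to-gray conversion, because the boundary stain lives in
#' a single channel. Pixel values are returned unmodified (TIFF integer counts
#' are preserved).
#'
#' @param path path to a TIFF or PNG file.
#' @param resolution pixel size in um/pixel, as recorded at acquisition.
#' @param channel optional 1-based channel index for multi-channel images.
#' @return A [raster_image()].
#' @export
read_image <- function(path, resolution, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    round(png::readPNG(path) * 255)
  } else stop("unsupported image format: .", ext)
  if (length(dim(a)) == 3L) {
    if (is.null(channel))
      stop("image has ", dim(a)[3], " channels; supply channel=")
    if (channel < 1L || channel > dim(a)[3])
      stop("channel out of range (image has ", dim(a)[3], " channels)")
    a <- a[, , channel]
  } else if (!is.null(channel) && channel != 1L) {
    stop("channel out of range (image is single-channel)")
  }
  raster_image(a, resolution)
}

#' Write a label image as a 16-bit TIFF
#'
#' @param labels integer matrix of region labels (0 = background/boundary).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels; cannot write 16-bit")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read back a 16-bit label TIFF written by [write_label_tiff()]
#' @param path path to the label TIFF.
#' @return Integer matrix of labels.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}
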