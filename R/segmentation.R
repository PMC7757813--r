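#' Marker-based watershed segmentation
#'
#' Stage 5. Floods the blurred ridge topography from the seed markers
#' (Meyer's algorithm, 4-connected flooding with a FIFO tie-break, so the
#' output is deterministic). Every usable pixel is assigned the label of
#' exactly one marker; pixels where two or more basins meet become watershed
#' lines and keep label 0, so a fiber's area never includes the shared
#' membrane midline. Label ids equal marker ids and marker pixels keep their
#' own label.
#'
#' @param markers a \code{marker_image} from [make_markers()], or an integer
#'   matrix of seeds (then \code{topography} must be given).
#' @param topography flooding surface, required when \code{markers} is a
#'   matrix.
#' @param mask optional logical matrix; FALSE pixels are excluded from
#'   flooding and stay 0 (used to keep connective-tissue areas out of the
#'   analysis).
#' @return Integer label matrix: 0 = watershed line / masked, 1..M = fibers.
#' @export
watershed_segment <- function(markers, topography = NULL, mask = NULL) {
  if (inherits(markers, "marker_image")) {
    topography <- markers$topography
    markers <- markers$markers
  }
  if (is.null(topography)) stop("topography required")
  if (!identical(dim(markers), dim(topography)))
    stop("markers and topography shapes differ")
  storage.mode(markers) <- "integer"
  if (max(markers) < 1L) stop("at least one marker is required")
  usable <- if (is.null(mask)) {
    matrix(TRUE, nrow(markers), ncol(markers))
  } else {
    if (!identical(dim(mask), dim(markers)))
      stop("mask and markers shapes differ")
    mask & TRUE
  }
  cpp_watershed(topography, markers, usable)
}

#' Exclude the membrane band from labeled fibers
#'
#' The line-detection philosophy places segmentation boundaries along the
#' membrane centrelines, i.e. halfway between fibers, so each watershed region
#' includes roughly half of every shared membrane of width w. Shrinking every
#' label by \code{half_width_px} around the watershed lines restores
#' interior-referenced regions, so CSA and Feret diameters describe the fiber
#' proper rather than midline-to-midline extents. Image borders are not
#' eroded, which preserves the touches-edge flag of border fibers.
#'
#' @param labels integer label matrix from [watershed_segment()].
#' @param half_width_px erosion radius in pixels (integer >= 0).
#' @return Label matrix with a widened 0-label boundary band.
#' @export
shrink_labels <- function(labels, half_width_px) {
  r <- as.integer(round(half_width_px))
  if (r < 1L) return(labels)
  lines0 <- labels == 0L
  if (!any(lines0)) return(labels)
  band <- EBImage::dilate(lines0 * 1, disk_kernel(r)) > 0.5
  out <- labels
  out[band] <- 0L
  out
}

#' Overlay label boundaries on an image
#'
#' Draws the boundaries of the segmented fibers on the original micrograph in
#' a contrasting colour; non-boundary pixels are left untouched.
#'
#' @param img a [raster_image()] or matrix (displayed on its own min-max
#'   range).
#' @param labels integer label matrix of the same shape.
#' @param color length-3 RGB in [0, 1] for the boundaries (default magenta).
#' @return RGB array (H x W x 3, values in [0, 1]).
#' @export
overlay_labels <- function(img, labels, color = c(1, 0, 1)) {
  p <- pixels_of(img)
  if (!identical(dim(p), dim(labels))) stop("image and labels shapes differ")
  sc <- rescale_255(p)
  base <- sc$pixels / 255
  nr <- nrow(labels); nc <- ncol(labels)
  b <- matrix(FALSE, nr, nc)
  b[-nr, ] <- b[-nr, ] | (labels[-nr, ] != labels[-1, ])
  b[-1, ]  <- b[-1, ]  | (labels[-1, ]  != labels[-nr, ])
  b[, -nc] <- b[, -nc] | (labels[, -nc] != labels[, -1])
  b[, -1]  <- b[, -1]  | (labels[, -1]  != labels[, -nc])
  out <- array(rep(base, 3L), c(nr, nc, 3L))
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[b] <- color[ch]
    out[, , ch] <- plane
  }
  out
}
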