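#' Estimate the slowly-varying staining background
#'
#' Stage 1a. Regional fluorescence of the fiber interiors varies across a
#' section with non-specific staining and tissue thickness. A large median
#' filter (kernel much wider than a boundary line, comparable to a fiber)
#' tracks the interior intensity while ignoring the thin bright boundaries.
#'
#' The kernel is a square of side \code{round(kernel_um / resolution)} pixels,
#' forced odd (+1 if even) so the median has a well-defined centre. Borders
#' are handled by reflection, which avoids the dark-edge artifacts that would
#' otherwise seed spurious ridges.
#'
#' @param img a [raster_image()].
#' @param kernel_um kernel side in micrometres (default 45).
#' @return A [raster_image()] holding the background estimate.
#' @seealso [level_image()]
#' @export
estimate_background <- function(img, kernel_um = 45) {
  stopifnot(inherits(img, "raster_image"))
  if (kernel_um <= 0) stop("kernel_um must be > 0")
  side <- round(um_to_px(kernel_um, img$resolution))
  if (side %% 2 == 0) side <- side + 1
  side <- max(side, 1L)
  if (side > min(dim(img$pixels)))
    stop("median kernel (", side, " px) larger than the image")
  rad <- (side - 1L) / 2L
  p <- img$pixels
  if (rad == 0) return(raster_image(p, img$resolution))
  mx <- max(p)
  if (mx <= 0) return(raster_image(p, img$resolution))
  # the median filter quantises [0, 1] data onto a 16-bit grid; integer
  # images (raw camera counts) are scaled so they sit exactly on that grid
  denom <- if (mx <= 65535 && all(p == round(p))) 65535 else mx
  padded <- reflect_pad(p, rad, rad) / denom
  med <- EBImage::medianFilter(padded, rad)
  out <- crop_pad(med, rad, rad, nrow(p), ncol(p)) * denom
  raster_image(out, img$resolution)
}

#' Level an image by its background estimate
#'
#' Stage 1b. Each pixel of the original image is divided by the background
#' estimate, yielding a real-valued "leveled" image in which fiber interiors
#' have a normalized intensity of ~1.0 and stained boundaries are > 1.0. The
#' operation is invariant to global intensity rescaling and, because the
#' background tracks smooth shading, approximately invariant to multiplicative
#' illumination gradients.
#'
#' @param img a [raster_image()] with raw intensities.
#' @param background background estimate from [estimate_background()];
#'   computed from \code{img} with \code{kernel_um} when \code{NULL}.
#' @param kernel_um median kernel side in um, used when \code{background} is
#'   \code{NULL}.
#' @param floor division guard: the divisor is \code{max(background, floor)}.
#'   Default is \code{1e-6 * max(img)}.
#' @return A [raster_image()] with real-valued leveled intensities.
#' @examples
#' img <- raster_image(matrix(100, 8, 8), 1)
#' lev <- level_image(img, kernel_um = 3)
#' range(lev$pixels)  # all 1: x / x
#' @export
level_image <- function(img, background = NULL, kernel_um = 45, floor = NULL) {
  stopifnot(inherits(img, "raster_image"))
  if (is.null(background)) background <- estimate_background(img, kernel_um)
  stopifnot(inherits(background, "raster_image"))
  if (!identical(dim(img$pixels), dim(background$pixels)))
    stop("image and background shapes differ")
  if (is.null(floor)) floor <- 1e-6 * max(img$pixels)
  if (floor <= 0) floor <- .Machine$double.xmin
  out <- img$pixels / pmax(background$pixels, floor)
  raster_image(out, img$resolution)
}
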