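#' Dilate the ridge skeleton
#'
#' Stage 4a. The raw centreline skeleton has gaps and single-pixel thickness;
#' morphological dilation with a Euclidean disk (radius 6 um by default)
#' thickens the detected lines so that the subsequent blur produces one smooth
#' barrier per boundary.
#'
#' @param ridges a \code{ridge_map} from [steger_ridges()], or a logical
#'   matrix.
#' @param radius_um disk radius in micrometres (> 0).
#' @param resolution um/pixel, required if \code{ridges} is a bare matrix.
#' @return Logical matrix, the dilated skeleton.
#' @export
dilate_ridges <- function(ridges, radius_um = 6, resolution = NULL) {
  if (radius_um <= 0) stop("radius_um must be > 0")
  sk <- if (inherits(ridges, "ridge_map")) ridges$skeleton else ridges
  res <- if (inherits(ridges, "ridge_map")) ridges$resolution
         else resolution_of(ridges, resolution)
  r <- round(um_to_px(radius_um, res))
  if (r < 1) return(sk)
  out <- EBImage::dilate(sk * 1, disk_kernel(r))
  out > 0.5
}

#' Blur the dilated ridge image
#'
#' Stage 4b. The dilated binary skeleton, on a 0/255 scale, is smoothed with a
#' Gaussian (reflective borders). The result is the watershed topography:
#' boundary crests near 255, fiber interiors near 0.
#'
#' @param dilated logical/binary matrix from [dilate_ridges()].
#' @param blur_sigma_um Gaussian sigma in micrometres (> 0).
#' @param resolution um/pixel.
#' @return Numeric matrix with values in [0, 255].
#' @export
blur_ridges <- function(dilated, blur_sigma_um = 3, resolution) {
  if (blur_sigma_um <= 0) stop("blur_sigma_um must be > 0")
  if (resolution <= 0) stop("resolution must be > 0")
  s <- um_to_px(blur_sigma_um, resolution)
  out <- gaussian_blur(dilated * 255, s)
  pmin(pmax(out, 0), 255)
}

#' Generate watershed markers from the blurred ridge image
#'
#' Stage 4c. Pixels strictly below the threshold form the seed support; its
#' 8-connected components of at least \code{min_seed_px} pixels become the
#' numbered markers for watershed flooding. The default threshold of 70 (on
#' the 0-255 scale) works across staining conditions; raising it enlarges and
#' merges seeds, lowering it shrinks them.
#'
#' @param blurred numeric matrix in [0, 255] from [blur_ridges()].
#' @param threshold seed threshold in (0, 255), default 70.
#' @param min_seed_px minimum component size in pixels (default 1).
#' @param mask optional logical matrix; FALSE pixels are never seeds.
#' @param exempt_frame if TRUE, components touching the image frame are kept
#'   as seeds regardless of \code{min_seed_px}. Partial fibers cut by the ROI
#'   edge often leave only a small sub-threshold remnant; giving them their
#'   own seed stops them being annexed by a neighbouring fiber's basin, so
#'   the neighbour is not dragged onto the edge and wrongly excluded. The
#'   pipeline enables this; the default reproduces the plain size rule.
#' @return An object of class \code{marker_image}: list with \code{markers}
#'   (integer matrix, 0 = unassigned, 1..M = seeds) and \code{topography}
#'   (the blurred image).
#' @export
make_markers <- function(blurred, threshold = 70, min_seed_px = 1L,
                         mask = NULL, exempt_frame = FALSE) {
  if (threshold <= 0 || threshold >= 255)
    stop("threshold must be in (0, 255)")
  support <- blurred < threshold
  if (!is.null(mask)) support <- support & mask
  comp <- cpp_label(support, 8L)
  if (max(comp) == 0L)
    stop("no seeds: every pixel is at or above the threshold (",
         threshold, "); increase seed_threshold and re-run")
  if (min_seed_px > 1L) {
    sizes <- tabulate(comp[comp > 0L], nbins = max(comp))
    keep <- sizes >= min_seed_px
    if (exempt_frame) {
      nr <- nrow(comp); nc <- ncol(comp)
      on_frame <- unique(c(comp[1, ], comp[nr, ], comp[, 1], comp[, nc]))
      keep[on_frame[on_frame > 0L]] <- TRUE
    }
    keep <- which(keep)
    if (length(keep) == 0L)
      stop("no seeds: all ", max(comp), " candidate seed regions are smaller ",
           "than min_seed_px = ", min_seed_px,
           "; increase seed_threshold and re-run")
    relab <- integer(max(comp) + 1L)
    relab[keep + 1L] <- seq_along(keep)
    comp <- matrix(relab[comp + 1L], nrow(comp), ncol(comp))
  }
  structure(list(markers = comp, topography = blurred),
            class = "marker_image")
}

#' @export
print.marker_image <- function(x, ...) {
  cat(sprintf("marker_image: %d seed regions on %d x %d px topography\n",
              max(x$markers), nrow(x$markers), ncol(x$markers)))
  invisible(x)
}

#' Preview the seed threshold
#'
#' Renders the sublevel set of the blurred ridge image that would become seed
#' support at a given threshold, mirroring an interactive threshold preview:
#' highlighted pixels count as "below threshold".
#'
#' @param blurred numeric matrix in [0, 255].
#' @param threshold candidate threshold.
#' @return RGB array (H x W x 3, values in [0, 1]); seed support in green.
#' @export
preview_threshold <- function(blurred, threshold = 70) {
  base <- pmin(pmax(blurred / 255, 0), 1)
  sel <- blurred < threshold
  out <- array(rep(base, 3L), c(nrow(blurred), ncol(blurred), 3L))
  g <- out[, , 2]; g[sel] <- 1; out[, , 2] <- g
  r <- out[, , 1]; r[sel] <- 0.2 * r[sel]; out[, , 1] <- r
  b <- out[, , 3]; b[sel] <- 0.2 * b[sel]; out[, , 3] <- b
  out
}
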