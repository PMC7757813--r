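#' Staining-contrast map
#'
#' Quality-control tool for staining protocols: the boundary-to-interior
#' staining contrast is read off the leveled image (fiber interiors ~1.0, so
#' a leveled boundary value is already a contrast ratio) sampled only at the
#' detected boundary centrelines, then locally averaged. Each output pixel is
#' the mean of the sampled centreline values within a square window (side 27
#' um by default, forced odd in pixels); windows containing no centreline
#' pixel get 0.
#'
#' @param leveled leveled image ([raster_image()] or matrix) from
#'   [level_image()].
#' @param ridges \code{ridge_map} from [steger_ridges()], or logical matrix.
#' @param kernel_um averaging window side in micrometres (default 27).
#' @param resolution um/pixel, required when both inputs are bare matrices.
#' @return Object of class \code{contrast_map}: list with \code{values}
#'   (matrix of ratio units, 0 where no boundary was sampled) and
#'   \code{resolution}.
#' @export
contrast_map <- function(leveled, ridges, kernel_um = 27, resolution = NULL) {
  if (kernel_um <= 0) stop("kernel_um must be > 0")
  p <- pixels_of(leveled)
  sk <- if (inherits(ridges, "ridge_map")) ridges$skeleton else ridges
  if (!identical(dim(p), dim(sk)))
    stop("leveled image and ridge skeleton shapes differ")
  res <- if (inherits(leveled, "raster_image")) leveled$resolution
         else if (inherits(ridges, "ridge_map")) ridges$resolution
         else resolution_of(leveled, resolution)
  if (!any(sk)) {
    warning("empty ridge skeleton: contrast map is all zero")
    return(structure(list(values = matrix(0, nrow(p), ncol(p)),
                          resolution = res), class = "contrast_map"))
  }
  side <- round(um_to_px(kernel_um, res))
  if (side %% 2 == 0) side <- side + 1
  side <- max(side, 1L)
  box <- matrix(1, side, side)
  skn <- sk * 1
  vals <- conv2_reflect(p * skn, box)
  cnt <- conv2_reflect(skn, box)
  out <- ifelse(cnt > 0.5, vals / pmax(cnt, .Machine$double.eps), 0)
  out[out < 0] <- 0
  structure(list(values = out, resolution = res), class = "contrast_map")
}

#' Adequate-contrast mask
#'
#' Regions whose local boundary/interior contrast ratio meets the threshold
#' segment reliably; a ratio of about 2.25 is the adequacy rule of thumb.
#'
#' @param map a \code{contrast_map}.
#' @param ratio_threshold contrast ratio threshold (> 0, default 2.25).
#' @return Logical matrix, TRUE where \code{map >= ratio_threshold}.
#' @export
contrast_ok_mask <- function(map, ratio_threshold = 2.25) {
  if (ratio_threshold <= 0) stop("ratio_threshold must be > 0")
  v <- if (inherits(map, "contrast_map")) map$values else map
  v >= ratio_threshold
}

#' @export
print.contrast_map <- function(x, ...) {
  cov <- x$values[x$values > 0]
  cat(sprintf("contrast_map: %d x %d px, %.1f%% covered, ratio range [%.2f, %.2f]\n",
              nrow(x$values), ncol(x$values),
              100 * length(cov) / length(x$values),
              if (length(cov)) min(cov) else NA, if (length(cov)) max(cov) else NA))
  invisible(x)
}

#' Render a contrast map as a pseudocolour image
#'
#' Display values are clipped to the 1.0-3.0 ratio range conventionally used
#' for contrast maps; raw values stay in the map object.
#'
#' @param map a \code{contrast_map}.
#' @param range display clip range (default c(1, 3)).
#' @return RGB array (H x W x 3), blue = low ratio, red = high, black = not
#'   sampled.
#' @export
render_contrast_map <- function(map, range = c(1, 3)) {
  v <- map$values
  t_ <- pmin(pmax((v - range[1]) / (range[2] - range[1]), 0), 1)
  covered <- v > 0
  out <- array(0, c(nrow(v), ncol(v), 3L))
  out[, , 1][covered] <- t_[covered]
  out[, , 3][covered] <- 1 - t_[covered]
  out[, , 2][covered] <- 0.2
  out
}
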