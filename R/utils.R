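# Internal numerical helpers shared by the filter stages.

# reflect-pad a matrix by (py, px) pixels on each side
reflect_pad <- function(m, py, px) {
  nr <- nrow(m); nc <- ncol(m)
  if (py >= nr || px >= nc)
    stop("padding exceeds image size; kernel too large for this image")
  ri <- c(rev(seq_len(py) + 1L), seq_len(nr), nr - seq_len(py))
  ci <- c(rev(seq_len(px) + 1L), seq_len(nc), nc - seq_len(px))
  m[ri, ci, drop = FALSE]
}

crop_pad <- function(m, py, px, nr, nc) {
  m[seq_len(nr) + py, seq_len(nc) + px, drop = FALSE]
}

# 2-D convolution with reflective boundary handling; kernel must have odd
# dimensions. filter2 is FFT-based circular convolution, so the image is
# reflect-padded by the kernel half-size first.
conv2_reflect <- function(m, kernel) {
  ky <- (nrow(kernel) - 1L) %/% 2L
  kx <- (ncol(kernel) - 1L) %/% 2L
  p <- reflect_pad(m, ky, kx)
  out <- EBImage::filter2(p, kernel, boundary = "circular")
  crop_pad(out, ky, kx, nrow(m), ncol(m))
}

# sampled 1-D Gaussian and its first two derivatives; zero-sum / unit-moment
# corrections keep derivative responses exact on linear and quadratic ramps
gaussian_kernel_1d <- function(sigma, order = 0L, radius = NULL) {
  stopifnot(sigma > 0)
  if (is.null(radius)) radius <- max(1L, ceiling(4 * sigma))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    g1 <- -x / sigma^2 * g
    g1 <- g1 - mean(g1)                  # zero response to constants
    g1 <- g1 / sum(-x * g1)              # unit response to slope 1
    return(g1)
  }
  if (order == 2L) {
    g2 <- (x^2 - sigma^2) / sigma^4 * g
    g2 <- g2 - mean(g2)                  # zero response to constants
    g2 <- g2 / sum(x^2 / 2 * g2)         # unit response to x^2/2
    return(g2)
  }
  stop("order must be 0, 1 or 2")
}

# separable Gaussian smoothing with reflective borders
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  g <- gaussian_kernel_1d(sigma_px, 0L)
  conv2_reflect(m, outer(g, g))
}

# Euclidean disk structuring element of integer radius r (in pixels)
disk_kernel <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 0)
  d <- seq(-r, r)
  outer(d, d, function(i, j) as.numeric(i^2 + j^2 <= r^2))
}

# linear map of a matrix to the 0-255 display range used by ridge detection
rescale_255 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi <= lo) return(list(pixels = array(0, dim(m)), lo = lo, hi = hi))
  list(pixels = (m - lo) / (hi - lo) * 255, lo = lo, hi = hi)
}

pixels_of <- function(img) {
  if (inherits(img, "raster_image")) img$pixels else img
}

resolution_of <- function(img, resolution = NULL) {
  if (!is.null(resolution)) return(resolution)
  if (inherits(img, "raster_image")) return(img$resolution)
  stop("resolution (um/pixel) must be supplied when the input is a bare matrix")
}
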