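#' Ridge-detection scale from the target line width
#'
#' The Gaussian scale of the curvilinear-structure detector is tied to the
#' width w of the boundary lines to be detected:
#' \deqn{\sigma = \frac{w}{2\sqrt{3}} + 0.5}
#' with w first converted from micrometres to pixels. At this scale the
#' second-derivative response at the centreline of a bar of width w is near
#' its maximum, which is what makes the detector selective for boundaries of
#' the stated width.
#'
#' @param w_um target boundary line width in micrometres (> 0); 6 um is the
#'   typical width of collagen-stained endomysium.
#' @param resolution um per pixel (> 0).
#' @return Gaussian scale in pixels (real).
#' @examples
#' sigma_from_linewidth(6, 0.462)  # 4.25 px
#' @export
sigma_from_linewidth <- function(w_um, resolution) {
  if (w_um <= 0) stop("w_um must be > 0")
  if (resolution <= 0) stop("resolution must be > 0")
  (w_um / resolution) / (2 * sqrt(3)) + 0.5
}

#' Steger curvilinear-structure (ridge) detection
#'
#' Stage 3. Locates the centrelines of the bright stained boundaries on the
#' enhanced 0-255 image and returns them as a 1-pixel-wide binary skeleton.
#'
#' The detector follows Steger's construction: Gaussian partial derivatives
#' r_x, r_y, r_xx, r_xy, r_yy are computed at scale \code{sigma_px}; at each
#' pixel the Hessian is eigen-decomposed and the eigenvector of the
#' largest-magnitude eigenvalue gives the direction n normal to the line. A
#' line point is accepted where the first directional derivative along n
#' vanishes inside the pixel (solved offset t with |t n| <= 0.5 per axis) and
#' the second directional derivative is negative (bright line). The salience
#' of a point is the magnitude of that second directional derivative.
#' Hysteresis linking keeps every connected chain of accepted points at
#' salience >= \code{low} that contains at least one point >= \code{high}.
#' By default \code{high} is set per image by a bimodal (Otsu) split of the
#' log saliences of accepted points -- noise responses and true boundary
#' responses differ by orders of magnitude, so the split lands in the valley
#' between them -- and \code{low = low_frac * high}. Chains are
#' rasterized to a thin binary skeleton (no 2x2 block of skeleton pixels);
#' sub-pixel centreline positions are retained in the result for diagnostics.
#'
#' @param img enhanced image on the 0-255 scale ([raster_image()] or matrix).
#' @param line_width_um target line width w in um, used to derive the scale.
#' @param sigma_px detection scale in pixels; overrides \code{line_width_um}.
#' @param low,high absolute hysteresis salience thresholds; if \code{NULL},
#'   derived per image as described above.
#' @param low_frac ratio of the low to the high threshold when derived
#'   automatically (default 0.25).
#' @param spur_prune_um remove terminal chain segments (spurs) shorter than
#'   this length; 0 (default) keeps all.
#' @param dark_lines detect dark lines instead of bright ones.
#' @param resolution um/pixel, required if \code{img} is a bare matrix.
#' @return An object of class \code{ridge_map}: list with \code{skeleton}
#'   (logical matrix), \code{salience} (matrix), \code{subpixel} (data.frame
#'   with 1-based \code{row}, \code{col} and sub-pixel \code{y}, \code{x}),
#'   \code{sigma_px}, \code{resolution}.
#' @export
steger_ridges <- function(img, line_width_um = 6, sigma_px = NULL,
                          low = NULL, high = NULL, low_frac = 0.25,
                          spur_prune_um = 0,
                          dark_lines = FALSE, resolution = NULL) {
  p <- pixels_of(img)
  res <- resolution_of(img, resolution)
  if (length(p) == 0L || nrow(p) < 3L || ncol(p) < 3L)
    stop("image too small for ridge detection")
  if (is.null(sigma_px)) sigma_px <- sigma_from_linewidth(line_width_um, res)
  if (sigma_px < 0.5) stop("sigma_px must be >= 0.5")
  if (dark_lines) p <- max(p) - p

  g0 <- gaussian_kernel_1d(sigma_px, 0L)
  g1 <- gaussian_kernel_1d(sigma_px, 1L)
  g2 <- gaussian_kernel_1d(sigma_px, 2L)
  rx  <- conv2_reflect(p, outer(g0, g1))
  ry  <- conv2_reflect(p, outer(g1, g0))
  rxx <- conv2_reflect(p, outer(g0, g2))
  ryy <- conv2_reflect(p, outer(g2, g0))
  rxy <- conv2_reflect(p, outer(g1, g1))

  # eigenvalue of the 2x2 Hessian with the largest magnitude, closed form
  tr <- rxx + ryy
  disc <- sqrt(pmax((rxx - ryy)^2 + 4 * rxy^2, 0))
  e1 <- (tr + disc) / 2
  e2 <- (tr - disc) / 2
  take1 <- abs(e1) >= abs(e2)
  lam <- ifelse(take1, e1, e2)
  # eigenvector (nx, ny) for lam: rows of (H - lam I) are orthogonal to it
  vx1 <- lam - ryy; vy1 <- rxy     # from second row: (rxy, ryy - lam)
  vx2 <- rxy;       vy2 <- lam - rxx
  use2 <- (vx2^2 + vy2^2) > (vx1^2 + vy1^2)
  nx <- ifelse(use2, vx2, vx1)
  ny <- ifelse(use2, vy2, vy1)
  nrm <- sqrt(nx^2 + ny^2)
  ok_dir <- nrm > 0
  nx <- ifelse(ok_dir, nx / pmax(nrm, .Machine$double.eps), 0)
  ny <- ifelse(ok_dir, ny / pmax(nrm, .Machine$double.eps), 0)

  # sub-pixel offset along n where the directional derivative vanishes;
  # second directional derivative along n equals lam
  denom <- lam
  t_off <- ifelse(abs(denom) > 0, -(rx * nx + ry * ny) / denom, Inf)
  # 0.51 rather than 0.5: a line centred exactly between two pixel rows
  # solves to |t| marginally above 0.5 on both neighbours and would
  # otherwise vanish
  within <- abs(t_off * nx) <= 0.51 & abs(t_off * ny) <= 0.51
  bright <- lam < 0
  valid <- ok_dir & bright & within & is.finite(t_off)
  salience <- ifelse(valid, -lam, 0)
  # drop numerical dust (FFT residues on flat regions) before thresholding
  sal_floor <- 1e-6 * max(salience)
  salience[salience <= sal_floor] <- 0

  pos <- salience[salience > 0]
  if (length(pos) == 0L) {
    skeleton <- matrix(FALSE, nrow(p), ncol(p))
    sub <- data.frame(row = integer(), col = integer(),
                      y = numeric(), x = numeric())
  } else {
    if (is.null(high)) high <- 10^otsu_threshold(log10(pos))
    if (is.null(low)) low <- low_frac * high
    if (low > high) low <- high
    weak <- salience >= low & valid & salience > 0
    comp <- cpp_label(weak, 8L)
    strong_ids <- unique(comp[salience >= high & weak])
    strong_ids <- strong_ids[strong_ids > 0]
    skeleton <- matrix(comp %in% strong_ids, nrow(p), ncol(p))
    skeleton <- thin_2x2(skeleton, salience)
    if (spur_prune_um > 0)
      skeleton <- prune_spurs(skeleton, round(um_to_px(spur_prune_um, res)))
    idx <- which(skeleton, arr.ind = TRUE)
    sub <- data.frame(row = idx[, 1], col = idx[, 2],
                      y = idx[, 1] + t_off[idx] * ny[idx],
                      x = idx[, 2] + t_off[idx] * nx[idx])
  }
  structure(list(skeleton = skeleton, salience = salience, subpixel = sub,
                 sigma_px = sigma_px, resolution = res),
            class = "ridge_map")
}

#' @export
print.ridge_map <- function(x, ...) {
  cat(sprintf("ridge_map: %d x %d px, %d centreline pixels (sigma = %.2f px)\n",
              nrow(x$skeleton), ncol(x$skeleton), sum(x$skeleton), x$sigma_px))
  invisible(x)
}

# Otsu's histogram threshold (maximal between-class variance) on a numeric
# vector; returns a value on the same scale
otsu_threshold <- function(v, nbins = 256L) {
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  h <- graphics::hist(v, breaks = seq(r[1], r[2], length.out = nbins + 1L),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sigma_b)]
}

# break every fully-true 2x2 block by dropping its least salient pixel
thin_2x2 <- function(sk, salience) {
  repeat {
    nr <- nrow(sk); nc <- ncol(sk)
    a <- sk[-nr, -nc] & sk[-1, -nc] & sk[-nr, -1] & sk[-1, -1]
    blk <- which(a, arr.ind = TRUE)
    if (nrow(blk) == 0L) break
    for (b in seq_len(nrow(blk))) {
      r <- blk[b, 1]; c <- blk[b, 2]
      if (!(sk[r, c] && sk[r + 1, c] && sk[r, c + 1] && sk[r + 1, c + 1]))
        next
      cells <- rbind(c(r, c), c(r + 1, c), c(r, c + 1), c(r + 1, c + 1))
      s <- salience[cells]
      kmin <- cells[which.min(s), , drop = FALSE]
      sk[kmin] <- FALSE
    }
  }
  sk
}

# iteratively remove endpoint pixels (<= 1 eight-neighbour) up to n_px times
prune_spurs <- function(sk, n_px) {
  for (i in seq_len(n_px)) {
    nb <- neighbor_count(sk)
    ends <- sk & nb <= 1L
    if (!any(ends)) break
    sk[ends] <- FALSE
  }
  sk
}

neighbor_count <- function(sk) {
  m <- matrix(0L, nrow(sk) + 2L, ncol(sk) + 2L)
  m[2:(nrow(sk) + 1L), 2:(ncol(sk) + 1L)] <- sk
  nr <- nrow(sk); nc <- ncol(sk)
  tot <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    tot <- tot + m[2:(nr + 1L) + dr, 2:(nc + 1L) + dc]
  }
  tot
}
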