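#' Specification of a synthetic muscle phantom
#'
#' The phantom emulates the image properties the segmentation pipeline
#' targets: a mosaic of convex polygonal fibers (Voronoi cells of a point
#' process, or a hexagonal lattice for analytic ground truth) separated by
#' bright boundary bands of fixed physical width, a smooth multiplicative
#' illumination gradient, a chosen boundary-to-interior staining contrast
#' ratio, and additive Gaussian pixel noise, discretized to 16-bit counts.
#'
#' @param width_px,height_px image size in pixels.
#' @param resolution um per pixel (default 0.462, a 20x slide-scanner pixel
#'   size).
#' @param layout \code{"hexagonal"} (regular lattice; every interior fiber
#'   has the same analytic minimum Feret diameter) or \code{"voronoi"}
#'   (Poisson-disk seeded mosaic with natural size variation).
#' @param pitch_um hexagonal lattice spacing = centre-to-centre = flat-to-flat
#'   distance of the undivided cells, in um. A hexagonal fiber's true minimum
#'   Feret is \code{pitch_um - boundary_width_um}.
#' @param mean_fiber_diameter_um target mean cell diameter for the Voronoi
#'   layout.
#' @param diameter_cv coefficient of variation of Voronoi cell diameters
#'   (controls packing irregularity).
#' @param boundary_width_um full width of the bright boundary band (default
#'   6, the typical stained endomysium width).
#' @param contrast_ratio boundary/interior intensity ratio (>= 1). A scalar
#'   gives uniform contrast; a length-2 vector gives a spatial pattern across
#'   x according to \code{contrast_layout}.
#' @param contrast_layout \code{"uniform"}, \code{"halves"} (left value,
#'   right value) or \code{"ramp"} (linear left to right).
#' @param illumination_gradient amplitude a in [0, 1) of a multiplicative
#'   linear gradient running left to right from (1 - a) to (1 + a).
#' @param noise_sd additive Gaussian noise SD as a fraction of the interior
#'   intensity (e.g. 0.05 = 5 percent).
#' @param interior_base interior intensity in counts (default 1000, within a
#'   10-bit camera range).
#' @param rng_seed integer seed; generation is bit-reproducible for a fixed
#'   spec.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(width_px = 1000L, height_px = 1000L,
                         resolution = 0.462,
                         layout = c("hexagonal", "voronoi"),
                         pitch_um = 51,
                         mean_fiber_diameter_um = 50,
                         diameter_cv = 0.2,
                         boundary_width_um = 6,
                         contrast_ratio = 2.5,
                         contrast_layout = c("uniform", "halves", "ramp"),
                         illumination_gradient = 0,
                         noise_sd = 0,
                         interior_base = 1000,
                         rng_seed = 1L) {
  layout <- match.arg(layout)
  contrast_layout <- match.arg(contrast_layout)
  if (length(contrast_ratio) == 1L) contrast_layout <- "uniform"
  if (any(contrast_ratio < 1)) stop("contrast_ratio must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (boundary_width_um <= 0) stop("boundary_width_um must be > 0")
  if (illumination_gradient < 0 || illumination_gradient >= 1)
    stop("illumination_gradient must be in [0, 1)")
  cell_um <- if (layout == "hexagonal") pitch_um else mean_fiber_diameter_um
  if (cell_um <= boundary_width_um)
    stop("degenerate mosaic: fiber diameter must exceed the boundary width")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 resolution = resolution, layout = layout,
                 pitch_um = pitch_um,
                 mean_fiber_diameter_um = mean_fiber_diameter_um,
                 diameter_cv = diameter_cv,
                 boundary_width_um = boundary_width_um,
                 contrast_ratio = contrast_ratio,
                 contrast_layout = contrast_layout,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd, interior_base = interior_base,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Generate a synthetic muscle phantom with ground truth
#'
#' Builds the mosaic described by a [phantom_spec()]: each pixel is assigned
#' to its nearest generating point; pixels whose second-nearest point is
#' nearly as close (difference of the two distances below the boundary width)
#' form the boundary band, which runs halfway between neighbouring cells.
#' Ground-truth fiber labels are the generating cells eroded by half the
#' boundary width, i.e. exactly the interior pixels, and the truth table is
#' computed from those labels with [measure_fibers()] -- the same measurement
#' code used on segmentations.
#'
#' The image is \code{interior_base * illumination(x)} inside fibers and
#' \code{contrast_ratio} times that on the boundary band, plus clipped
#' additive Gaussian noise, rounded to 16-bit integer counts.
#'
#' @param spec a [phantom_spec()].
#' @return List of class \code{phantom} with \code{image} (a
#'   [raster_image()]), \code{truth} (list: \code{labels} integer matrix,
#'   \code{table} the ground-truth \code{fiber_table}) and \code{spec}.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  res <- spec$resolution
  w <- spec$width_px; h <- spec$height_px
  wb_px <- um_to_px(spec$boundary_width_um, res)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$rng_seed)

  ctr <- if (spec$layout == "hexagonal") {
    hex_centers(w, h, um_to_px(spec$pitch_um, res))
  } else {
    poisson_disk_centers(w, h, um_to_px(spec$mean_fiber_diameter_um, res),
                         spec$diameter_cv)
  }
  cell_px <- um_to_px(if (spec$layout == "hexagonal") spec$pitch_um
                      else spec$mean_fiber_diameter_um, res)
  nn <- two_nearest_blocked(h, w, ctr$x, ctr$y, cell_px)
  gap <- sqrt(nn$d2) - sqrt(nn$d1)   # ~2 x distance to the cell interface
  interior <- gap > wb_px
  labels <- nn$nearest
  labels[!interior] <- 0L
  storage.mode(labels) <- "integer"
  labels <- drop_empty_labels(labels)

  # intensity model
  xg <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  illum <- 1 + spec$illumination_gradient * (2 * xg / max(w - 1, 1) - 1)
  ratio <- switch(spec$contrast_layout,
    uniform = matrix(spec$contrast_ratio[1], h, w),
    halves = ifelse(xg < w / 2, spec$contrast_ratio[1], spec$contrast_ratio[2]),
    ramp = matrix(spec$contrast_ratio[1] +
                    (spec$contrast_ratio[2] - spec$contrast_ratio[1]) *
                    xg / max(w - 1, 1), h, w))
  img <- spec$interior_base * illum
  img[!interior] <- img[!interior] * ratio[!interior]
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(length(img),
                              sd = spec$noise_sd * spec$interior_base)
  img <- round(pmin(pmax(img, 0), 65535))

  truth_tab <- measure_fibers(labels, res)
  structure(list(image = raster_image(img, res),
                 truth = list(labels = labels, table = truth_tab),
                 spec = spec),
            class = "phantom")
}

#' Ground-truth morphometrics of a phantom
#'
#' Recomputes the per-fiber table from the truth labels via
#' [measure_fibers()], the single source of measurement logic, and annotates
#' it with the standard exclusion rules.
#'
#' @param phantom a \code{phantom} from [generate_phantom()].
#' @param csa_min_um2,csa_max_um2,exclude_edges exclusion rules, as in
#'   [filter_fibers()].
#' @return An annotated \code{fiber_table}.
#' @export
truth_table <- function(phantom, csa_min_um2 = 200, csa_max_um2 = 10000,
                        exclude_edges = TRUE) {
  stopifnot(inherits(phantom, "phantom"))
  tab <- measure_fibers(phantom$truth$labels, phantom$spec$resolution)
  filter_fibers(tab, csa_min_um2, csa_max_um2, exclude_edges)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %s layout, %d x %d px at %.4g um/px, %d true fibers\n",
              x$spec$layout, nrow(x$image$pixels), ncol(x$image$pixels),
              x$spec$resolution, max(x$truth$labels)))
  invisible(x)
}

# staggered triangular lattice whose Voronoi cells are regular hexagons with
# flat-to-flat distance = pitch; centres extend past the borders so edge
# cells exist
hex_centers <- function(w, h, pitch_px) {
  dy <- pitch_px * sqrt(3) / 2
  rows <- seq(-pitch_px, h + pitch_px, by = dy)
  xs <- NULL; ys <- NULL
  for (i in seq_along(rows)) {
    offset <- if (i %% 2 == 0) pitch_px / 2 else 0
    cx <- seq(-pitch_px + offset, w + pitch_px, by = pitch_px)
    xs <- c(xs, cx)
    ys <- c(ys, rep(rows[i], length(cx)))
  }
  list(x = xs, y = ys)
}

# dart-throwing Poisson-disk sampler. The number of generating points is set
# so that the mean Voronoi cell matches the requested mean fiber diameter
# (hexagonal-packing equivalent area), and the minimum spacing shrinks with
# the requested diameter CV: looser packings produce more size variation.
# Sampling stops at the target count rather than at saturation, which keeps
# the mean cell size at the requested value.
poisson_disk_centers <- function(w, h, mean_d_px, cv) {
  rmin <- mean_d_px * max(1 - 2 * cv, 0.2)
  margin <- mean_d_px
  area <- (w + 2 * margin) * (h + 2 * margin)
  n_target <- max(4L, round(area / (sqrt(3) / 2 * mean_d_px^2)))
  xs <- numeric(0); ys <- numeric(0)
  fails <- 0L
  while (length(xs) < n_target && fails < 5000L) {
    px <- stats::runif(1, -margin, w + margin)
    py <- stats::runif(1, -margin, h + margin)
    if (length(xs) == 0L || min((xs - px)^2 + (ys - py)^2) >= rmin^2) {
      xs <- c(xs, px); ys <- c(ys, py)
      fails <- 0L
    } else fails <- fails + 1L
  }
  list(x = xs, y = ys)
}

# block-wise two-nearest-centre assignment: each tile only consults centres
# within a safety margin of a few cell diameters, keeping the cost linear in
# pixels rather than pixels x centres
two_nearest_blocked <- function(h, w, cx, cy, cell_px, block = 256L) {
  d1 <- matrix(0, h, w); d2 <- matrix(0, h, w)
  nearest <- matrix(0L, h, w)
  margin <- 4 * cell_px
  for (r0 in seq(1L, h, by = block)) {
    r1 <- min(r0 + block - 1L, h)
    for (c0 in seq(1L, w, by = block)) {
      c1 <- min(c0 + block - 1L, w)
      # 0-based pixel coords of this tile: rows r0-1..r1-1, cols c0-1..c1-1
      sel <- which(cx >= (c0 - 1) - margin & cx <= (c1 - 1) + margin &
                   cy >= (r0 - 1) - margin & cy <= (r1 - 1) + margin)
      if (length(sel) < 2L) sel <- seq_along(cx)   # degenerate: use all
      sub <- cpp_two_nearest(r1 - r0 + 1L, c1 - c0 + 1L,
                             cx[sel] - (c0 - 1), cy[sel] - (r0 - 1))
      d1[r0:r1, c0:c1] <- sub$d1
      d2[r0:r1, c0:c1] <- sub$d2
      nearest[r0:r1, c0:c1] <- matrix(sel[sub$nearest],
                                      r1 - r0 + 1L, c1 - c0 + 1L)
    }
  }
  list(d1 = d1, d2 = d2, nearest = nearest)
}

# relabel to contiguous 1..N (some generating points fall outside the frame)
drop_empty_labels <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(labels)
  relab <- integer(max(ids) + 1L)
  relab[ids + 1L] <- seq_along(ids)
  out <- matrix(relab[labels + 1L], nrow(labels), ncol(labels))
  storage.mode(out) <- "integer"
  out
}
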