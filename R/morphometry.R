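#' Minimum and maximum Feret diameter of a point set
#'
#' Computes the caliper extremes of a planar point set from its convex hull:
#' the minimum Feret diameter (smallest width over all orientations) by
#' rotating calipers -- for a convex polygon the minimum width is attained
#' with one caliper flat on a hull edge, so it is the minimum over hull edges
#' of the farthest vertex distance from the edge line -- and the maximum Feret
#' diameter as the largest inter-vertex distance of the hull.
#'
#' The minimum Feret diameter is the preferred size measure for muscle fibers
#' because it is the least affected by oblique sectioning distortion.
#'
#' @param pts two-column matrix of (x, y) coordinates.
#' @return Named numeric vector \code{c(min = ..., max = ...)}, in the units
#'   of \code{pts}.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' feret_diameters(sq)  # min 1, max sqrt(2)
#' @export
feret_diameters <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) == 1L) return(c(min = 0, max = 0))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n == 2L) {
    d <- sqrt(sum((hp[1, ] - hp[2, ])^2))
    return(c(min = 0, max = d))
  }
  # min width: per hull edge, max distance of vertices from the edge line
  nxt <- c(2:n, 1L)
  ex <- hp[nxt, 1] - hp[, 1]
  ey <- hp[nxt, 2] - hp[, 2]
  elen <- sqrt(ex^2 + ey^2)
  keep <- elen > 0
  wmin <- Inf
  for (i in which(keep)) {
    # distance of all vertices from the line through edge i
    d <- abs((hp[, 1] - hp[i, 1]) * ey[i] - (hp[, 2] - hp[i, 2]) * ex[i]) /
      elen[i]
    wmin <- min(wmin, max(d))
  }
  dmax <- max(stats::dist(hp))
  c(min = wmin, max = dmax)
}

#' Measure CSA, Feret diameters and location of every labeled fiber
#'
#' Per label: cross-sectional area as pixel count times resolution squared;
#' minimum and maximum Feret diameter from the convex hull of the pixel
#' *corner* points (so a 1-pixel-wide object has width one pixel, not zero),
#' converted to micrometres; centroid in 0-based pixel-centre coordinates; and
#' a flag for touching the image border.
#'
#' @param labels integer label matrix (0 = background, 1..N = fibers).
#' @param resolution um per pixel.
#' @return A \code{fiber_table}: a data frame with columns \code{fiber_id},
#'   \code{csa_um2}, \code{min_feret_um}, \code{max_feret_um},
#'   \code{centroid_x_px}, \code{centroid_y_px}, \code{touches_edge},
#'   \code{excluded_reason}, with the resolution and detection counts stored
#'   as attributes.
#' @export
measure_fibers <- function(labels, resolution) {
  if (resolution <= 0) stop("resolution must be > 0")
  idx <- which(labels > 0L)
  if (length(idx) == 0L) stop("no positive labels to measure")
  nr <- nrow(labels)
  nc <- ncol(labels)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  by_label <- split(seq_along(idx), labels[idx])
  recs <- lapply(names(by_label), function(id) {
    sel <- by_label[[id]]
    r <- rows[sel]; cc <- cols[sel]
    npx <- length(sel)
    # extreme pixels per column are enough for the corner-point hull
    o <- order(cc, r)
    cs <- cc[o]; rs <- r[o]
    first <- !duplicated(cs)
    last <- rev(!duplicated(rev(cs)))
    ucol <- cs[first]; rmin <- rs[first]; rmax <- rs[last]
    cx <- c(ucol - 1L, ucol, ucol - 1L, ucol, ucol - 1L, ucol, ucol - 1L, ucol)
    cy <- c(rmin - 1L, rmin - 1L, rmin, rmin,
            rmax - 1L, rmax - 1L, rmax, rmax)
    fer <- feret_diameters(cbind(cx, cy))
    data.frame(
      fiber_id = as.integer(id),
      csa_um2 = npx * resolution^2,
      min_feret_um = fer[["min"]] * resolution,
      max_feret_um = fer[["max"]] * resolution,
      centroid_x_px = mean(cc) - 0.5,
      centroid_y_px = mean(r) - 0.5,
      touches_edge = any(r == 1L | r == nr | cc == 1L | cc == nc),
      excluded_reason = "none",
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, recs)
  tab <- tab[order(tab$fiber_id), , drop = FALSE]
  rownames(tab) <- NULL
  fiber_table(tab, resolution)
}

fiber_table <- function(df, resolution, counts = NULL) {
  if (is.null(counts))
    counts <- list(n_detected = nrow(df),
                   n_kept = sum(df$excluded_reason == "none"),
                   frac_below = 0, frac_above = 0)
  structure(df, resolution = resolution, counts = counts,
            class = c("fiber_table", "data.frame"))
}

#' Apply size- and edge-based fiber exclusion rules
#'
#' Segments with CSA outside \code{[csa_min_um2, csa_max_um2]} are excluded:
#' undersized segments are typically artifacts misread as small fibers, and
#' oversized ones are typically groups of fibers merged into one object.
#' Fibers intersecting the image/ROI border are excluded when
#' \code{exclude_edges} is TRUE, since their true extent is unknown. Excluded
#' fractions are reported over all detected fibers.
#'
#' @param table a \code{fiber_table} from [measure_fibers()].
#' @param csa_min_um2,csa_max_um2 acceptable CSA range in um^2.
#' @param exclude_edges drop border-touching fibers (default TRUE).
#' @return The annotated \code{fiber_table}; kept fibers have
#'   \code{excluded_reason == "none"}, and the \code{counts} attribute holds
#'   \code{n_detected}, \code{n_kept}, \code{frac_below}, \code{frac_above}.
#' @export
filter_fibers <- function(table, csa_min_um2 = 200, csa_max_um2 = 10000,
                          exclude_edges = TRUE) {
  if (csa_min_um2 >= csa_max_um2) stop("csa_min_um2 must be < csa_max_um2")
  reason <- rep("none", nrow(table))
  reason[table$csa_um2 < csa_min_um2] <- "below_csa"
  reason[table$csa_um2 > csa_max_um2] <- "above_csa"
  if (exclude_edges)
    reason[reason == "none" & table$touches_edge] <- "edge"
  table$excluded_reason <- reason
  n <- nrow(table)
  counts <- list(
    n_detected = n,
    n_kept = sum(reason == "none"),
    frac_below = sum(reason == "below_csa") / n,
    frac_above = sum(reason == "above_csa") / n)
  fiber_table(as.data.frame(table), attr(table, "resolution"), counts)
}

#' Summarize kept fibers
#'
#' Mean and sample standard deviation (n - 1) of the kept minimum-Feret
#' diameters, plus their histogram.
#'
#' @param table an annotated \code{fiber_table} (see [filter_fibers()]).
#' @param bin_width_um histogram bin width in micrometres (default 5).
#' @return List with \code{n_detected}, \code{n_kept}, \code{frac_below_csa},
#'   \code{frac_above_csa}, \code{mean_min_feret_um}, \code{sd_min_feret_um}
#'   and \code{histogram} (data frame \code{bin_left_um}, \code{count}).
#' @export
summarize_fibers <- function(table, bin_width_um = 5) {
  if (bin_width_um <= 0) stop("bin_width_um must be > 0")
  counts <- attr(table, "counts")
  kept <- table$min_feret_um[table$excluded_reason == "none"]
  if (length(kept) == 0L) {
    warning("no kept fibers: mean/SD undefined")
    return(list(n_detected = counts$n_detected, n_kept = 0L,
                frac_below_csa = counts$frac_below,
                frac_above_csa = counts$frac_above,
                mean_min_feret_um = NA_real_, sd_min_feret_um = NA_real_,
                histogram = data.frame(bin_left_um = numeric(),
                                       count = integer())))
  }
  breaks <- seq(0, (max(kept) %/% bin_width_um + 1) * bin_width_um,
                by = bin_width_um)
  h <- graphics::hist(kept, breaks = breaks, plot = FALSE, right = FALSE)
  list(n_detected = counts$n_detected,
       n_kept = length(kept),
       frac_below_csa = counts$frac_below,
       frac_above_csa = counts$frac_above,
       mean_min_feret_um = mean(kept),
       sd_min_feret_um = if (length(kept) > 1L) stats::sd(kept) else NA_real_,
       histogram = data.frame(bin_left_um = h$breaks[-length(h$breaks)],
                              count = h$counts))
}

#' @export
print.fiber_table <- function(x, ...) {
  counts <- attr(x, "counts")
  cat(sprintf("fiber_table: %d fibers detected, %d kept (%.4g um/px)\n",
              counts$n_detected, counts$n_kept, attr(x, "resolution")))
  print(as.data.frame(utils::head(x, 10L)))
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}
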