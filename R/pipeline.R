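#' Segment myofibers in a muscle cross-section micrograph
#'
#' Runs the full five-stage pipeline on a single-channel fluorescence image
#' of a muscle cross-section with boundary (membrane / extracellular-matrix)
#' staining:
#' \enumerate{
#'   \item intensity leveling: divide by a 45 um median-filter background
#'     estimate ([level_image()]);
#'   \item contrast enhancement: Perona-Malik anisotropic diffusion, then a
#'     4th-power boost and linear rescale to 0-255 ([pm_diffuse()],
#'     [power_boost()]);
#'   \item ridge detection: Steger curvilinear-structure detection of the
#'     boundary centrelines ([steger_ridges()]);
#'   \item seed generation: disk dilation, Gaussian blur and thresholding of
#'     the skeleton ([dilate_ridges()], [blur_ridges()], [make_markers()]);
#'   \item marker-based watershed segmentation, followed by CSA/Feret
#'     morphometry and exclusion rules ([watershed_segment()],
#'     [measure_fibers()], [filter_fibers()]).
#' }
#' The pipeline is deterministic: identical input and configuration give an
#' identical result.
#'
#' @param img a [raster_image()] (see [read_image()]).
#' @param config a [pipeline_config()].
#' @param mask optional logical matrix (TRUE = analyze); FALSE areas, e.g.
#'   connective tissue, are excluded from seeding and flooding.
#' @param keep_intermediates retain the per-stage images in the result
#'   (leveled, enhanced, skeleton, topography) for debugging or display.
#' @param verbose print per-stage progress and timing.
#' @return Object of class \code{fiber_segmentation}: list with
#'   \code{labels} (integer matrix), \code{fibers} (annotated
#'   \code{fiber_table}), \code{summary} (run summary incl. configuration
#'   echo and exclusion bookkeeping), \code{config}, \code{image}, and
#'   optionally \code{intermediates}.
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_spec(width_px = 400, height_px = 400,
#'                                     noise_sd = 0.03, rng_seed = 7))
#' seg <- segment_fibers(ph$image)
#' summary(seg)
#' }
#' @export
segment_fibers <- function(img, config = pipeline_config(), mask = NULL,
                           keep_intermediates = FALSE, verbose = FALSE) {
  stopifnot(inherits(img, "raster_image"))
  validate_config(config)
  if (!is.null(mask) && !identical(dim(mask), dim(img$pixels)))
    stop("mask and image shapes differ")
  res <- img$resolution
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    if (verbose) message(sprintf("[%s] %.2fs", stage, timings[[stage]]))
    out
  }

  leveled <- tick("leveling", level_image(
    img, kernel_um = config$median_kernel_um,
    floor = config$level_floor_frac * max(img$pixels)))
  diffused <- tick("diffusion", pm_diffuse(
    leveled, sigma_um = config$pm_sigma_um,
    iterations = config$pm_iterations, timestep = config$pm_timestep,
    conductance = config$pm_conductance))
  boosted <- tick("boost", power_boost(diffused, config$boost_exponent))
  enhanced <- rescale_display(boosted)
  ridges <- tick("ridge_detection", steger_ridges(
    enhanced, line_width_um = config$line_width_um,
    low = config$ridge_low_contrast, high = config$ridge_high_contrast,
    low_frac = config$ridge_low_frac,
    spur_prune_um = config$spur_prune_um))
  if (!any(ridges$skeleton))
    stop("stage 'ridge_detection': no ridges detected; the image may lack ",
         "boundary contrast", call. = FALSE)
  dilated <- tick("dilation", dilate_ridges(ridges, config$dilate_radius_um))
  topo <- tick("blur", blur_ridges(dilated, config$blur_sigma_um, res))
  min_seed_px <- config$min_seed_px
  if (is.null(min_seed_px))
    min_seed_px <- max(1L, floor(config$csa_min_um2 / res^2 / 4))
  markers <- tick("seeding", make_markers(
    topo, threshold = config$seed_threshold, min_seed_px = min_seed_px,
    mask = mask, exempt_frame = TRUE))
  # an auxiliary marker on the image frame catches partial border fibers that
  # have no seed of their own, so they cannot annex an interior fiber's basin
  # and drag it onto the edge; its region is dropped after flooding. A fiber
  # is an edge fiber when its sub-threshold basin connects to the frame (its
  # interior visibly continues past the ROI).
  mk <- markers$markers
  border_id <- max(mk) + 1L
  nr <- nrow(mk); nc <- ncol(mk)
  frame_idx <- rbind(cbind(1L, seq_len(nc)), cbind(nr, seq_len(nc)),
                     cbind(seq_len(nr), 1L), cbind(seq_len(nr), nc))
  free <- mk[frame_idx] == 0L
  mk[frame_idx[free, , drop = FALSE]] <- border_id
  labels <- tick("watershed", watershed_segment(
    mk, topography = markers$topography, mask = mask))
  edge_ids <- frame_connected_labels(labels, markers$topography,
                                     config$seed_threshold)
  labels[labels == border_id] <- 0L
  if (config$membrane_compensation) {
    half_w <- round(um_to_px(config$line_width_um, res) / 2)
    labels <- tick("membrane_compensation", shrink_labels(labels, half_w))
  }
  fibers <- tick("morphometry", measure_fibers(labels, res))
  fibers$touches_edge <- fibers$touches_edge | fibers$fiber_id %in% edge_ids
  fibers <- filter_fibers(fibers, config$csa_min_um2, config$csa_max_um2,
                          config$exclude_edge_fibers)
  stats <- summarize_fibers(fibers, config$hist_bin_um)

  run_summary <- list(
    n_detected = stats$n_detected,
    n_kept = stats$n_kept,
    frac_below_csa = stats$frac_below_csa,
    frac_above_csa = stats$frac_above_csa,
    mean_min_feret_um = stats$mean_min_feret_um,
    sd_min_feret_um = stats$sd_min_feret_um,
    n_markers = max(markers$markers),
    n_skeleton_px = sum(ridges$skeleton),
    display_rescale = list(lo = attr(enhanced$pixels, "scale_lo"),
                           hi = attr(enhanced$pixels, "scale_hi")),
    resolution_um_per_px = res,
    min_seed_px = min_seed_px,
    stage_seconds = as.list(timings),
    config = unclass(config),
    histogram = stats$histogram)

  out <- list(labels = labels, fibers = fibers, summary = run_summary,
              config = config, image = img)
  if (keep_intermediates)
    out$intermediates <- list(leveled = leveled, enhanced = enhanced,
                              ridges = ridges, dilated = dilated,
                              topography = topo, markers = markers)
  structure(out, class = "fiber_segmentation")
}

# labels whose sub-threshold basin connects to the image frame: the fiber's
# dark interior continues to the ROI edge, so the fiber is a partial (edge)
# fiber regardless of where the watershed placed its outer boundary
frame_connected_labels <- function(labels, topography, threshold) {
  support <- topography < threshold
  comp <- cpp_label(support, 8L)
  nr <- nrow(comp); nc <- ncol(comp)
  frame_ids <- unique(c(comp[1, ], comp[nr, ], comp[, 1], comp[, nc]))
  frame_ids <- frame_ids[frame_ids > 0L]
  if (length(frame_ids) == 0L) return(integer(0))
  ids <- unique(labels[support & matrix(comp %in% frame_ids, nr, nc)])
  ids[ids > 0L]
}

#' @export
print.fiber_segmentation <- function(x, ...) {
  s <- x$summary
  cat("fiber_segmentation\n")
  cat(sprintf("  image: %d x %d px at %.4g um/px\n",
              nrow(x$labels), ncol(x$labels), s$resolution_um_per_px))
  cat(sprintf("  fibers: %d detected, %d kept (%.1f%% below / %.1f%% above CSA range)\n",
              s$n_detected, s$n_kept, 100 * s$frac_below_csa,
              100 * s$frac_above_csa))
  if (!is.na(s$mean_min_feret_um))
    cat(sprintf("  min Feret: mean %.2f um (SD %.2f)\n",
                s$mean_min_feret_um, s$sd_min_feret_um))
  invisible(x)
}

#' @export
summary.fiber_segmentation <- function(object, ...) {
  s <- object$summary
  cat("Myofiber segmentation summary\n")
  cat(sprintf("  detected objects:        %d\n", s$n_detected))
  cat(sprintf("  kept fibers:             %d\n", s$n_kept))
  cat(sprintf("  excluded below %g um^2:  %.2f%%\n",
              s$config$csa_min_um2, 100 * s$frac_below_csa))
  cat(sprintf("  excluded above %g um^2:  %.2f%%\n",
              s$config$csa_max_um2, 100 * s$frac_above_csa))
  cat(sprintf("  mean min Feret:          %.2f um\n", s$mean_min_feret_um))
  cat(sprintf("  SD min Feret:            %.2f um\n", s$sd_min_feret_um))
  invisible(s)
}

#' @export
plot.fiber_segmentation <- function(x, type = c("overlay", "histogram"), ...) {
  type <- match.arg(type)
  if (type == "overlay") {
    ov <- overlay_labels(x$image, x$labels)
    grDevices::dev.hold()
    graphics::plot.new()
    graphics::plot.window(c(0, ncol(x$labels)), c(0, nrow(x$labels)),
                          asp = 1)
    graphics::rasterImage(ov, 0, 0, ncol(x$labels), nrow(x$labels))
    grDevices::dev.flush()
  } else {
    kept <- x$fibers$min_feret_um[x$fibers$excluded_reason == "none"]
    graphics::hist(kept, breaks = seq(0, max(kept) + x$config$hist_bin_um,
                                      by = x$config$hist_bin_um),
                   xlab = "minimum Feret diameter (um)", main = "Kept fibers",
                   ...)
  }
  invisible(x)
}

#' Write segmentation outputs to a directory
#'
#' Emits the standard result file set: \code{labels.tif} (16-bit label
#' image), \code{overlay.png} (boundaries drawn on the input),
#' \code{fibers.csv} (per-fiber morphometrics), \code{summary.json}
#' (counts, excluded fractions, mean/SD and configuration echo) and
#' \code{feret_histogram.csv}.
#'
#' @param x a \code{fiber_segmentation}, or an integer label matrix.
#' @param outdir output directory (created if missing).
#' @param fibers,summary when \code{x} is a matrix: the annotated
#'   \code{fiber_table} and run-summary list to write.
#' @param image optional [raster_image()] for the overlay when \code{x} is a
#'   matrix.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(x, outdir, fibers = NULL, summary = NULL,
                          image = NULL) {
  if (inherits(x, "fiber_segmentation")) {
    labels <- x$labels; fibers <- x$fibers; summary <- x$summary
    image <- x$image
  } else {
    labels <- x
    if (is.null(fibers) || is.null(summary))
      stop("fibers and summary are required when x is a label matrix")
    kept_ids <- fibers$fiber_id[fibers$excluded_reason == "none"]
    if (!all(kept_ids %in% labels))
      stop("labels/table inconsistent: kept fiber ids missing from labels")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  f <- file.path(outdir, "labels.tif")
  write_label_tiff(labels, f); files <- c(files, f)

  if (!is.null(image)) {
    f <- file.path(outdir, "overlay.png")
    png::writePNG(overlay_labels(image, labels), f); files <- c(files, f)
  }

  f <- file.path(outdir, "fibers.csv")
  utils::write.csv(as.data.frame(fibers)[, c(
    "fiber_id", "csa_um2", "min_feret_um", "max_feret_um",
    "centroid_x_px", "centroid_y_px", "touches_edge", "excluded_reason")],
    f, row.names = FALSE); files <- c(files, f)

  hist_df <- if (!is.null(summary$histogram)) summary$histogram else {
    data.frame(bin_left_um = numeric(), count = integer())
  }
  f <- file.path(outdir, "feret_histogram.csv")
  utils::write.csv(hist_df, f, row.names = FALSE); files <- c(files, f)

  f <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary[setdiff(names(summary), "histogram")], f,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
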