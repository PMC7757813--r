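#' Pipeline configuration
#'
#' All length-like parameters are given in micrometres and converted to pixels
#' internally via the image resolution, so one configuration transfers across
#' images of different magnification. Defaults are the operating point for
#' collagen/laminin-type boundary staining at 0.3-0.5 um/pixel.
#'
#' @param median_kernel_um side of the square median-filter kernel used to
#'   estimate the slowly-varying background (default 45).
#' @param pm_sigma_um diffusion filter width sigma in um (default 3); the
#'   conductance threshold is derived as \code{k = sigma^2 / resolution^2},
#'   see [k_from_sigma()].
#' @param pm_iterations number of explicit diffusion steps (default 15).
#' @param pm_timestep explicit-scheme time step, must be in (0, 0.25] for
#'   2-D stability (default 0.2).
#' @param pm_conductance conductance function, \code{"exponential"}
#'   (\eqn{e^{-(\nabla/k)^2}}) or \code{"rational"}
#'   (\eqn{1/(1+(\nabla/k)^2)}).
#' @param boost_exponent power applied to the diffused, leveled image to
#'   amplify boundary contrast (default 4).
#' @param line_width_um target boundary line width w for ridge detection
#'   (default 6); the detection scale is \code{w/(2*sqrt(3)) + 0.5} px, see
#'   [sigma_from_linewidth()].
#' @param ridge_low_contrast,ridge_high_contrast absolute hysteresis salience
#'   thresholds; if \code{NULL} (default) the high threshold is derived per
#'   image by a bimodal (Otsu) split of the log ridge saliences and the low
#'   threshold as \code{ridge_low_frac} times it (see [steger_ridges()]).
#' @param ridge_low_frac low/high hysteresis threshold ratio used when
#'   absolute thresholds are not given (default 0.25).
#' @param spur_prune_um prune skeleton spurs shorter than this length
#'   (default 0 = keep all; dilation + blur absorbs small spurs).
#' @param dilate_radius_um radius of the disk structuring element that
#'   thickens the ridge skeleton before blurring (default 6).
#' @param blur_sigma_um Gaussian blur sigma applied to the dilated binary
#'   ridge image (default 3, half the default line width).
#' @param seed_threshold watershed-seed threshold on the 0-255 blurred ridge
#'   image; pixels strictly below it form seeds (default 70).
#' @param min_seed_px minimum seed component size in pixels; \code{NULL}
#'   (default) uses a quarter of the pixel area of the smallest acceptable
#'   fiber (\code{csa_min_um2}).
#' @param csa_min_um2,csa_max_um2 acceptable fiber cross-sectional area range
#'   in um^2 (defaults 200 and 10000); segments outside it are excluded.
#' @param exclude_edge_fibers drop fibers touching the image/ROI border
#'   (default TRUE).
#' @param membrane_compensation if TRUE (default), the measured fiber regions
#'   are shrunk by half the configured line width before morphometry, so that
#'   diameters refer to the fiber interior rather than membrane-midline to
#'   membrane-midline. See the methods vignette for the rationale.
#' @param contrast_kernel_um side of the square averaging window of the
#'   staining-contrast map (default 27).
#' @param contrast_ok_ratio boundary/interior contrast ratio above which
#'   staining is adequate for reliable segmentation (default 2.25).
#' @param hist_bin_um bin width of the minimum-Feret histogram (default 5).
#' @param level_floor_frac division guard for leveling, as a fraction of the
#'   image maximum (default 1e-6).
#' @return An object of class \code{pipeline_config}.
#' @examples
#' cfg <- pipeline_config(seed_threshold = 60)
#' cfg$seed_threshold
#' @export
pipeline_config <- function(median_kernel_um = 45,
                            pm_sigma_um = 3,
                            pm_iterations = 15L,
                            pm_timestep = 0.2,
                            pm_conductance = c("exponential", "rational"),
                            boost_exponent = 4,
                            line_width_um = 6,
                            ridge_low_contrast = NULL,
                            ridge_high_contrast = NULL,
                            ridge_low_frac = 0.25,
                            spur_prune_um = 0,
                            dilate_radius_um = 6,
                            blur_sigma_um = 3,
                            seed_threshold = 70,
                            min_seed_px = NULL,
                            csa_min_um2 = 200,
                            csa_max_um2 = 10000,
                            exclude_edge_fibers = TRUE,
                            membrane_compensation = TRUE,
                            contrast_kernel_um = 27,
                            contrast_ok_ratio = 2.25,
                            hist_bin_um = 5,
                            level_floor_frac = 1e-6) {
  pm_conductance <- match.arg(pm_conductance)
  cfg <- list(
    median_kernel_um = median_kernel_um, pm_sigma_um = pm_sigma_um,
    pm_iterations = as.integer(pm_iterations), pm_timestep = pm_timestep,
    pm_conductance = pm_conductance, boost_exponent = boost_exponent,
    line_width_um = line_width_um,
    ridge_low_contrast = ridge_low_contrast,
    ridge_high_contrast = ridge_high_contrast,
    ridge_low_frac = ridge_low_frac,
    spur_prune_um = spur_prune_um,
    dilate_radius_um = dilate_radius_um, blur_sigma_um = blur_sigma_um,
    seed_threshold = seed_threshold, min_seed_px = min_seed_px,
    csa_min_um2 = csa_min_um2, csa_max_um2 = csa_max_um2,
    exclude_edge_fibers = isTRUE(exclude_edge_fibers),
    membrane_compensation = isTRUE(membrane_compensation),
    contrast_kernel_um = contrast_kernel_um,
    contrast_ok_ratio = contrast_ok_ratio,
    hist_bin_um = hist_bin_um, level_floor_frac = level_floor_frac)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  um_fields <- c("median_kernel_um", "pm_sigma_um", "line_width_um",
                 "dilate_radius_um", "blur_sigma_um", "contrast_kernel_um",
                 "hist_bin_um")
  for (f in um_fields)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop(f, " must be > 0 (um)")
  if (cfg$spur_prune_um < 0) stop("spur_prune_um must be >= 0")
  if (cfg$pm_iterations < 0) stop("pm_iterations must be >= 0")
  if (cfg$pm_timestep <= 0 || cfg$pm_timestep > 0.25)
    stop("pm_timestep must be in (0, 0.25] (explicit-scheme stability)")
  if (cfg$boost_exponent < 1) stop("boost_exponent must be >= 1")
  if (cfg$seed_threshold <= 0 || cfg$seed_threshold >= 255)
    stop("seed_threshold must be in (0, 255)")
  if (cfg$csa_min_um2 >= cfg$csa_max_um2)
    stop("csa_min_um2 must be < csa_max_um2")
  if (cfg$csa_min_um2 <= 0) stop("csa_min_um2 must be > 0")
  if (cfg$contrast_ok_ratio <= 0) stop("contrast_ok_ratio must be > 0")
  if (!is.null(cfg$ridge_low_contrast) || !is.null(cfg$ridge_high_contrast)) {
    lo <- cfg$ridge_low_contrast; hi <- cfg$ridge_high_contrast
    if (is.null(lo) || is.null(hi) || lo < 0 || lo > hi)
      stop("ridge thresholds must satisfy 0 <= low <= high")
  }
  if (cfg$ridge_low_frac <= 0 || cfg$ridge_low_frac > 1)
    stop("ridge_low_frac must be in (0, 1]")
  if (cfg$level_floor_frac <= 0) stop("level_floor_frac must be > 0")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("fiber segmentation pipeline configuration:\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-22s %s\n", f,
                if (is.null(v)) "(auto)" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}
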