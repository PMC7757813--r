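#' Mean minimum-Feret percent error against ground truth
#'
#' The headline accuracy metric: the percent difference between the mean
#' kept minimum-Feret diameter of a segmentation and that of the ground
#' truth, \eqn{100 |m_{pred} - m_{truth}| / m_{truth}}. The absolute value is
#' returned; the signed difference is attached as attribute
#' \code{"signed_pct"}.
#'
#' @param pred,truth annotated \code{fiber_table}s (see [filter_fibers()]);
#'   only kept fibers enter the means.
#' @return Percent error (non-negative numeric).
#' @examples
#' # pred mean 46 vs truth mean 50 -> 8 percent
#' @export
mean_feret_error <- function(pred, truth) {
  mp <- kept_mean(pred, "pred")
  mt <- kept_mean(truth, "truth")
  out <- 100 * abs(mp - mt) / mt
  attr(out, "signed_pct") <- 100 * (mp - mt) / mt
  out
}

kept_mean <- function(tab, what) {
  v <- tab$min_feret_um[tab$excluded_reason == "none"]
  if (length(v) == 0L) stop("no kept fibers in ", what, " table")
  mean(v)
}

#' Bland-Altman agreement analysis
#'
#' For paired per-image summaries (method A vs method B), computes the
#' per-pair mean \eqn{m = (A+B)/2} and difference \eqn{d = A-B}, the ordinary
#' least-squares regression of d on m (a nonzero slope indicates
#' magnitude-dependent bias) and the mean bias with 95 percent limits of
#' agreement.
#'
#' @param pairs two-column matrix or data frame of paired values (A, B), one
#'   row per image; at least 3 pairs.
#' @return List with \code{slope}, \code{intercept}, \code{mean_bias},
#'   \code{loa} (mean bias +/- 1.96 SD of d) and \code{p_slope}.
#' @export
bland_altman <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  if (nrow(pairs) < 3L) stop("need at least 3 pairs")
  m <- (pairs[, 1] + pairs[, 2]) / 2
  d <- pairs[, 1] - pairs[, 2]
  if (stats::var(m) == 0)
    stop("slope undefined: all pair means are identical")
  fit <- stats::lm(d ~ m)
  co <- stats::coef(fit)
  p_slope <- tryCatch(summary(fit)$coefficients["m", "Pr(>|t|)"],
                      error = function(e) NA_real_)
  sd_d <- stats::sd(d)
  list(slope = unname(co["m"]), intercept = unname(co["(Intercept)"]),
       mean_bias = mean(d),
       loa = c(lower = mean(d) - 1.96 * sd_d, upper = mean(d) + 1.96 * sd_d),
       p_slope = p_slope)
}

#' Signed fiber-count percent error
#'
#' \eqn{100 (n_{pred} - n_{truth}) / n_{truth}} over kept fibers; positive
#' values indicate over-segmentation (single fibers subdivided and counted
#' multiply), the typical failure mode around artifacts.
#'
#' @param pred,truth annotated \code{fiber_table}s.
#' @return Signed percent (numeric).
#' @export
count_error <- function(pred, truth) {
  np <- sum(pred$excluded_reason == "none")
  nt <- sum(truth$excluded_reason == "none")
  if (nt < 1L) stop("truth table has no kept fibers")
  100 * (np - nt) / nt
}
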