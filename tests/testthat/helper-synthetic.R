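# Shared synthetic fixtures and independent oracles, built in code.

# axis-aligned or oblique bright bar of full width w_px through the image
# centre (integer pixel) at angle theta_deg; returns image + a function giving
# signed distance of (x, y) from the true centreline
make_bar <- function(n = 400, w_px = 12, theta_deg = 0, amp = 200, bg = 10,
                     half_len = 150) {
  c0 <- n / 2
  x <- matrix(rep(seq_len(n), each = n), n, n)
  y <- matrix(rep(seq_len(n), n), n, n)
  if (theta_deg == 0) {            # horizontal: runs along x
    d <- y - c0
    along <- x - c0
  } else if (theta_deg == 90) {    # vertical: runs along y
    d <- x - c0
    along <- y - c0
  } else {
    th <- theta_deg * pi / 180
    d <- -(x - c0) * sin(th) + (y - c0) * cos(th)
    along <- (x - c0) * cos(th) + (y - c0) * sin(th)
  }
  img <- bg + amp * (abs(d) <= w_px / 2 & abs(along) <= half_len)
  dist_fn <- function(px, py) {
    if (theta_deg == 0) py - c0
    else if (theta_deg == 90) px - c0
    else {
      th <- theta_deg * pi / 180
      -(px - c0) * sin(th) + (py - c0) * cos(th)
    }
  }
  along_fn <- function(px, py) {
    if (theta_deg == 0) px - c0
    else if (theta_deg == 90) py - c0
    else {
      th <- theta_deg * pi / 180
      (px - c0) * cos(th) + (py - c0) * sin(th)
    }
  }
  list(img = img, dist = dist_fn, along = along_fn, half_len = half_len)
}

# random convex polygon: convex hull of random points
rand_convex_polygon <- function(n_pts = 12, scale = 50) {
  p <- cbind(stats::runif(n_pts, 0, scale), stats::runif(n_pts, 0, scale))
  p[grDevices::chull(p), , drop = FALSE]
}

# brute-force Feret oracle: width of the point set projected on directions
# swept at fine angular resolution
feret_bruteforce <- function(pts, step_deg = 0.1) {
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  widths <- vapply(th, function(a) {
    pr <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    max(pr) - min(pr)
  }, numeric(1))
  c(min = min(widths), max = max(widths))
}

# reference Perona-Malik explicit scheme: straightforward loops, 4-neighbour
# fluxes, no-flux borders (independent of the vectorised implementation)
pm_reference <- function(m, k, iterations, dt,
                         conductance = c("exponential", "rational")) {
  conductance <- match.arg(conductance)
  g <- if (conductance == "exponential") function(s) exp(-(s / k)^2)
       else function(s) 1 / (1 + (s / k)^2)
  nr <- nrow(m); nc <- ncol(m)
  for (it in seq_len(iterations)) {
    out <- m
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        acc <- 0
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          ii <- i + d[1]; jj <- j + d[2]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
            df <- m[ii, jj] - m[i, j]
            acc <- acc + g(abs(df)) * df
          }
        }
        out[i, j] <- m[i, j] + dt * acc
      }
    }
    m <- out
  }
  m
}

# the validation phantom: hexagonal mosaic at slide-scanner resolution with
# ~45 um fibers, 6 um boundaries, moderate gradient and noise
validation_phantom_spec <- function(rng_seed, contrast_ratio = 2.5,
                                    noise_sd = 0.05,
                                    illumination_gradient = 0.3) {
  phantom_spec(width_px = 1000L, height_px = 1000L, resolution = 0.462,
               layout = "hexagonal", pitch_um = 51, boundary_width_um = 6,
               contrast_ratio = contrast_ratio,
               illumination_gradient = illumination_gradient,
               noise_sd = noise_sd, rng_seed = rng_seed)
}
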