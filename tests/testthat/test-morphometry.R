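test_that("Feret diameters of simple shapes are analytic", {
  sq <- cbind(c(0, 4, 4, 0), c(0, 0, 3, 3))
  f <- feret_diameters(sq)
  expect_equal(f[["min"]], 3)
  expect_equal(f[["max"]], 5)

  seg <- cbind(c(0, 3), c(0, 4))
  fs <- feret_diameters(seg)
  expect_equal(fs[["min"]], 0)
  expect_equal(fs[["max"]], 5)
})

test_that("rotating calipers agrees with the brute-force sweep", {
  set.seed(123)
  worst <- 0
  for (i in 1:100) {
    poly <- rand_convex_polygon(n_pts = sample(5:25, 1))
    rc <- feret_diameters(poly)
    bf <- feret_bruteforce(poly)
    worst <- max(worst,
                 abs(rc[["min"]] - bf[["min"]]) / bf[["min"]],
                 abs(rc[["max"]] - bf[["max"]]) / bf[["max"]])
  }
  expect_lt(worst, 0.005)
})

test_that("labeled rectangles and disks measure correctly", {
  lab <- matrix(0L, 30, 40)
  lab[5:12, 6:25] <- 1L   # 8 x 20 px rectangle
  res <- 0.5
  tab <- measure_fibers(lab, res)
  expect_equal(tab$csa_um2, 8 * 20 * res^2)
  expect_equal(tab$min_feret_um, 8 * res)
  expect_equal(tab$max_feret_um, sqrt(8^2 + 20^2) * res)
  expect_false(tab$touches_edge)
  expect_equal(tab$centroid_y_px, mean(5:12) - 0.5)
  expect_equal(tab$centroid_x_px, mean(6:25) - 0.5)

  # digitised disk of radius r: with the pixel-corner convention every
  # caliper width lies within one pixel of 2r + 0.5 (axis-aligned extent is
  # 2r + 1; the tightest oblique caliper is slightly below 2r + 0.5)
  r <- 9
  d <- seq(-14, 14)
  disk <- outer(d, d, function(i, j) as.integer(i^2 + j^2 <= r^2))
  tabd <- measure_fibers(disk, 1)
  expect_lt(abs(tabd$min_feret_um - (2 * r + 0.5)), 1)
  expect_lt(abs(tabd$max_feret_um - (2 * r + 0.5)), 1)
  expect_true(tabd$min_feret_um <= tabd$max_feret_um)
})

test_that("an edge-touching label is flagged", {
  lab <- matrix(0L, 10, 10); lab[1:3, 4:6] <- 1L
  expect_true(measure_fibers(lab, 1)$touches_edge)
})

test_that("Feret measures are robust to 17-degree rotation", {
  a <- 30; b <- 20
  rasterize <- function(theta) {
    d <- seq(-45, 45)
    x <- matrix(rep(d, each = length(d)), length(d))
    y <- matrix(rep(d, length(d)), length(d))
    th <- theta * pi / 180
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), length(d))
  }
  f0 <- measure_fibers(rasterize(0), 1)
  f17 <- measure_fibers(rasterize(17), 1)
  expect_lt(abs(f17$min_feret_um - f0$min_feret_um) / f0$min_feret_um, 0.02)
  expect_lt(abs(f17$max_feret_um - f0$max_feret_um) / f0$max_feret_um, 0.02)
})

test_that("CSA partition conserves the image area", {
  ph <- generate_phantom(phantom_spec(width_px = 260, height_px = 260,
    resolution = 0.7, layout = "hexagonal", pitch_um = 45,
    boundary_width_um = 6, contrast_ratio = 2.5, rng_seed = 6))
  lab <- ph$truth$labels
  tab <- measure_fibers(lab, 0.7)
  expect_equal(sum(tab$csa_um2) + sum(lab == 0L) * 0.7^2,
               260 * 260 * 0.7^2, tolerance = 1e-9)
  expect_true(all(tab$min_feret_um <= tab$max_feret_um))
  expect_true(all(tab$csa_um2 > 0))
})

test_that("size and edge exclusion rules follow hand counts", {
  df <- data.frame(
    fiber_id = 1:3,
    csa_um2 = c(150, 500, 12000),
    min_feret_um = c(10, 25, 120), max_feret_um = c(12, 30, 150),
    centroid_x_px = 0, centroid_y_px = 0,
    touches_edge = FALSE, excluded_reason = "none",
    stringsAsFactors = FALSE)
  tab <- fiberseg:::fiber_table(df, 1)
  out <- filter_fibers(tab, 200, 10000, exclude_edges = TRUE)
  cts <- attr(out, "counts")
  expect_equal(cts$n_kept, 1L)
  expect_equal(cts$frac_below, 1 / 3)
  expect_equal(cts$frac_above, 1 / 3)
  expect_equal(out$excluded_reason, c("below_csa", "none", "above_csa"))

  # widening the range never reduces the kept count
  k1 <- attr(filter_fibers(tab, 200, 10000), "counts")$n_kept
  k2 <- attr(filter_fibers(tab, 100, 20000), "counts")$n_kept
  expect_gte(k2, k1)

  # all in range, none on edge: kept = detected
  df2 <- df; df2$csa_um2 <- c(300, 500, 900)
  out2 <- filter_fibers(fiberseg:::fiber_table(df2, 1), 200, 10000)
  expect_equal(attr(out2, "counts")$n_kept, 3L)
})

test_that("summaries report mean, SD and a conserving histogram", {
  df <- data.frame(
    fiber_id = 1:3, csa_um2 = c(500, 600, 700),
    min_feret_um = c(40, 50, 60), max_feret_um = c(45, 55, 65),
    centroid_x_px = 0, centroid_y_px = 0,
    touches_edge = FALSE, excluded_reason = "none",
    stringsAsFactors = FALSE)
  s <- summarize_fibers(filter_fibers(fiberseg:::fiber_table(df, 1)))
  expect_equal(s$mean_min_feret_um, 50)
  expect_equal(s$sd_min_feret_um, 10)
  expect_equal(sum(s$histogram$count), 3L)

  one <- summarize_fibers(filter_fibers(fiberseg:::fiber_table(df[1, ], 1)))
  expect_true(is.na(one$sd_min_feret_um))

  df$excluded_reason <- "edge"
  tab <- fiberseg:::fiber_table(df, 1)
  expect_warning(s0 <- summarize_fibers(tab), "no kept fibers")
  expect_true(is.na(s0$mean_min_feret_um))
})
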