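test_that("detection scale formula matches hand arithmetic", {
  expect_equal(sigma_from_linewidth(6, 0.462), (6 / 0.462) / (2 * sqrt(3)) + 0.5)
  expect_equal(sigma_from_linewidth(6, 0.368), (6 / 0.368) / (2 * sqrt(3)) + 0.5)
  expect_equal(sigma_from_linewidth(1e-9, 1), 0.5, tolerance = 1e-6)
  expect_error(sigma_from_linewidth(0, 1), "w_um")
  expect_error(sigma_from_linewidth(6, -1), "resolution")
})

test_that("a flat image yields an empty skeleton", {
  r <- steger_ridges(matrix(5, 60, 60), resolution = 1, line_width_um = 6)
  expect_false(any(r$skeleton))
  expect_error(steger_ridges(matrix(5, 2, 2), resolution = 1), "too small")
})

test_that("bar centrelines are recovered to sub-pixel accuracy", {
  for (w in c(8, 12, 16)) {
    for (theta in c(0, 30, 90)) {
      bar <- make_bar(w_px = w, theta_deg = theta)
      sg <- sigma_from_linewidth(w * 0.462, 0.462)
      r <- steger_ridges(bar$img, sigma_px = sg, resolution = 0.462)
      sp <- r$subpixel
      core <- abs(bar$along(sp$x, sp$y)) <= bar$half_len - 10
      expect_gt(sum(core), 200)  # detected along the bar
      dd <- abs(bar$dist(sp$x[core], sp$y[core]))
      expect_gte(mean(dd <= 0.5), 0.95)
    }
  }
})

test_that("two parallel bars give two disjoint chains", {
  w <- 10
  n <- 300
  m <- matrix(10, n, n)
  r1 <- 120; r2 <- 120 + 3 * w
  m[(r1 - w/2):(r1 + w/2), 40:260] <- 210
  m[(r2 - w/2):(r2 + w/2), 40:260] <- 210
  r <- steger_ridges(m, sigma_px = sigma_from_linewidth(w, 1), resolution = 1)
  comp <- fiberseg:::cpp_label(r$skeleton, 8L)
  expect_equal(max(comp), 2L)
  # the chains are dominated by the two true centreline rows (a few pixels
  # near the bar tips wander, but stay attached to their chain)
  rows <- which(r$skeleton, arr.ind = TRUE)[, 1]
  expect_gt(mean(rows %in% c(r1, r2)), 0.8)
  expect_true(all(abs(rows - r1) <= w | abs(rows - r2) <= w))
})

test_that("the skeleton is thin: no 2x2 block of skeleton pixels", {
  bar <- make_bar(w_px = 9, theta_deg = 30)
  r <- steger_ridges(bar$img, sigma_px = sigma_from_linewidth(9, 1),
                     resolution = 1)
  sk <- r$skeleton
  nr <- nrow(sk); nc <- ncol(sk)
  blocks <- sk[-nr, -nc] & sk[-1, -nc] & sk[-nr, -1] & sk[-1, -1]
  expect_false(any(blocks))
})

test_that("salience at the centreline peaks near the prescribed scale", {
  # for an ideal bar of half-width a the centreline response
  # |(box * g'')(0)| = 2a g(a)/sigma^2 is maximal at sigma = a/sqrt(3) =
  # w/(2 sqrt(3)) -- the scale-selection rationale of the formula
  w <- 12
  bar <- make_bar(w_px = w, theta_deg = 0)
  sg_star <- w / (2 * sqrt(3))
  sweep <- seq(0.5 * sg_star, 2 * sg_star, length.out = 13)
  sal <- vapply(sweep, function(sg) {
    r <- steger_ridges(bar$img, sigma_px = sg, resolution = 1)
    max(r$salience[200, ])
  }, numeric(1))
  best <- sweep[which.max(sal)]
  step <- diff(sweep)[1]
  expect_lte(abs(best - sg_star), step + 1e-9)
})

test_that("rotated bars localise within one pixel on average", {
  bar <- make_bar(w_px = 12, theta_deg = 30)
  r <- steger_ridges(bar$img, sigma_px = sigma_from_linewidth(12, 1),
                     resolution = 1)
  sp <- r$subpixel
  core <- abs(bar$along(sp$x, sp$y)) <= 130
  expect_lt(mean(abs(bar$dist(sp$x[core], sp$y[core]))), 1)
})
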