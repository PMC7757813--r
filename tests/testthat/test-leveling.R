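test_that("median background of a constant image is the constant", {
  img <- raster_image(matrix(7, 20, 20), 1)
  bg <- estimate_background(img, kernel_um = 5)
  expect_equal(bg$pixels, matrix(7, 20, 20))
})

test_that("a 3x3 median removes an isolated bright pixel", {
  p <- matrix(10, 15, 15); p[8, 8] <- 1000
  img <- raster_image(p, 1)
  bg <- estimate_background(img, kernel_um = 3)
  expect_equal(bg$pixels, matrix(10, 15, 15))
})

test_that("kernel side is rounded from um and forced odd", {
  # 45 um at 0.462 um/px -> 97.4 px -> 97 (odd already): a 97x97 kernel on a
  # 96-px image must be rejected, on a 97-px image accepted
  img_small <- raster_image(matrix(1, 96, 96), 0.462)
  expect_error(estimate_background(img_small, 45), "larger than the image")
  img_ok <- raster_image(matrix(1, 97, 97), 0.462)
  expect_silent(estimate_background(img_ok, 45))
  # 20 um at 1 um/px -> 20 px -> forced odd 21: rejected on a 20-px image
  expect_error(estimate_background(raster_image(matrix(1, 20, 20), 1), 20),
               "larger than the image")
})

test_that("leveling divides out the background exactly", {
  p <- matrix(100, 12, 12)
  img <- raster_image(p, 1)
  lev <- level_image(img, kernel_um = 3)
  expect_equal(lev$pixels, matrix(1, 12, 12))

  # interior 100, boundary 250, flat background 100
  p2 <- matrix(100, 12, 12); p2[6, ] <- 250
  lev2 <- level_image(raster_image(p2, 1),
                      background = raster_image(matrix(100, 12, 12), 1))
  expect_equal(lev2$pixels[6, 3], 2.5)
  expect_equal(lev2$pixels[2, 3], 1.0)
})

test_that("a zero background is guarded by the floor", {
  p <- matrix(c(0, 5), 10, 10)
  lev <- level_image(raster_image(p, 1),
                     background = raster_image(matrix(0, 10, 10), 1),
                     floor = 1e-6)
  expect_true(all(is.finite(lev$pixels)))
})

test_that("leveling is invariant to global intensity scaling", {
  ph <- generate_phantom(phantom_spec(width_px = 220, height_px = 220,
    resolution = 1, layout = "hexagonal", pitch_um = 45, boundary_width_um = 6,
    contrast_ratio = 2.0, noise_sd = 0.03, rng_seed = 5))
  l1 <- level_image(ph$image, kernel_um = 45)
  # integer-preserving scaling: exact (the median is a selection and the
  # 16-bit quantisation grid is untouched)
  l2 <- level_image(raster_image(ph$image$pixels * 3, 1), kernel_um = 45)
  expect_equal(l2$pixels, l1$pixels, tolerance = 1e-12)
  # arbitrary scaling: invariant up to the 16-bit quantiser of the median
  l3 <- level_image(raster_image(ph$image$pixels * 3.7, 1), kernel_um = 45)
  expect_equal(l3$pixels, l1$pixels, tolerance = 2e-3)
})

test_that("leveling compensates a slowly-varying multiplicative gradient", {
  # at 2 um/px the 45 um kernel spans 23 px, so a +-30% linear gradient over
  # 600 px varies ~2.3% per kernel width: the slowly-varying regime
  ph <- generate_phantom(phantom_spec(width_px = 600, height_px = 600,
    resolution = 2, layout = "hexagonal", pitch_um = 51, boundary_width_um = 6,
    contrast_ratio = 2.5, noise_sd = 0, rng_seed = 3))
  W <- 600
  s <- matrix(rep(seq(0.85, 1.15, length.out = W), each = W), W, W)
  d <- abs(level_image(raster_image(ph$image$pixels * s, 2))$pixels -
             level_image(ph$image)$pixels)
  expect_lt(max(d), 0.02)
})

test_that("shape mismatches are rejected", {
  expect_error(level_image(raster_image(matrix(1, 4, 4), 1),
                           background = raster_image(matrix(1, 5, 5), 1)),
               "shapes differ")
})
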