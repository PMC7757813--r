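test_that("generation is deterministic for a fixed seed and leaves RNG alone", {
  spec <- phantom_spec(width_px = 200, height_px = 200, resolution = 1,
                       layout = "voronoi", mean_fiber_diameter_um = 40,
                       noise_sd = 0.05, rng_seed = 99)
  set.seed(1); before <- runif(1)
  set.seed(1)
  p1 <- generate_phantom(spec)
  after <- runif(1)
  p2 <- generate_phantom(spec)
  expect_identical(p1$image$pixels, p2$image$pixels)
  expect_identical(p1$truth$labels, p2$truth$labels)
  expect_equal(before, after)  # caller RNG stream restored
})

test_that("a noiseless flat-illumination phantom has exactly two intensities", {
  ph <- generate_phantom(phantom_spec(width_px = 150, height_px = 150,
    resolution = 1, layout = "hexagonal", pitch_um = 40, boundary_width_um = 6,
    contrast_ratio = 2.5, illumination_gradient = 0, noise_sd = 0,
    rng_seed = 1))
  expect_setequal(unique(as.vector(ph$image$pixels)), c(1000, 2500))
})

test_that("hexagonal truth has the analytic minimum Feret diameter", {
  pitch <- 50; wb <- 6
  ph <- generate_phantom(phantom_spec(width_px = 400, height_px = 400,
    resolution = 1, layout = "hexagonal", pitch_um = pitch,
    boundary_width_um = wb, contrast_ratio = 2.5, rng_seed = 2))
  tab <- truth_table(ph)
  kept <- tab[tab$excluded_reason == "none", ]
  expect_gt(nrow(kept), 20)
  expect_true(all(abs(kept$min_feret_um - (pitch - wb)) <= 1))
})

test_that("the boundary band width and sample ratio match the spec", {
  ph <- generate_phantom(phantom_spec(width_px = 300, height_px = 300,
    resolution = 1, layout = "hexagonal", pitch_um = 50, boundary_width_um = 6,
    contrast_ratio = 2.0, noise_sd = 0.04, rng_seed = 3))
  bnd <- ph$truth$labels == 0L
  ratio <- mean(ph$image$pixels[bnd]) / mean(ph$image$pixels[!bnd])
  expect_equal(ratio, 2.0, tolerance = 0.02)
})

test_that("truth CSA lies in the biological range for 20-100 um fibers", {
  for (d in c(25, 60, 95)) {
    ph <- generate_phantom(phantom_spec(width_px = 500, height_px = 500,
      resolution = 1, layout = "hexagonal", pitch_um = d,
      boundary_width_um = 6, contrast_ratio = 2.5, rng_seed = 7))
    tab <- truth_table(ph)
    kept <- tab[tab$excluded_reason == "none", ]
    expect_true(all(kept$csa_um2 >= 200 & kept$csa_um2 <= 10000))
  }
})

test_that("voronoi diameter variability tracks the requested CV", {
  ph <- generate_phantom(phantom_spec(width_px = 900, height_px = 900,
    resolution = 1, layout = "voronoi", mean_fiber_diameter_um = 50,
    diameter_cv = 0.2, boundary_width_um = 6, contrast_ratio = 2.5,
    rng_seed = 4))
  tab <- truth_table(ph)
  kept <- tab$min_feret_um[tab$excluded_reason == "none"]
  expect_gte(length(kept), 200)
  cv <- stats::sd(kept) / mean(kept)
  expect_gte(cv, 0.1)
  expect_lte(cv, 0.3)
})

test_that("truth table is measure_fibers applied to the truth labels", {
  ph <- generate_phantom(phantom_spec(width_px = 200, height_px = 200,
    resolution = 1, layout = "hexagonal", pitch_um = 45, boundary_width_um = 6,
    contrast_ratio = 2.5, rng_seed = 5))
  direct <- measure_fibers(ph$truth$labels, 1)
  via <- truth_table(ph, exclude_edges = FALSE)
  expect_equal(via$min_feret_um, direct$min_feret_um)
  expect_equal(via$csa_um2, direct$csa_um2)
})

test_that("degenerate mosaics are rejected", {
  expect_error(phantom_spec(pitch_um = 5, boundary_width_um = 6), "degenerate")
  expect_error(phantom_spec(contrast_ratio = 0.5), "contrast_ratio")
  expect_error(phantom_spec(illumination_gradient = 1.2), "illumination")
})
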