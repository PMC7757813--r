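test_that("raster_image validates its invariants", {
  expect_s3_class(raster_image(matrix(0, 1, 1), 0.462), "raster_image")
  expect_error(raster_image(matrix(-1, 2, 2), 0.5), "non-negative")
  expect_error(raster_image(matrix(0, 2, 2), 0), "resolution")
  expect_error(raster_image(array(0, c(2, 2, 2)), 0.5), "matrix")
  expect_error(raster_image(matrix(NA_real_, 2, 2), 0.5), "finite")
})

test_that("um_to_px matches hand arithmetic and is linear", {
  expect_equal(um_to_px(45, 0.462), 45 / 0.462)
  expect_equal(um_to_px(6, 0.368), 6 / 0.368)
  expect_equal(um_to_px(0, 0.37), 0)
  expect_error(um_to_px(5, 0), "resolution")
  set.seed(1)
  a <- runif(20, 0, 100); b <- runif(20, 0, 100); r <- runif(20, 0.1, 2)
  expect_equal(um_to_px(a + b, r), um_to_px(a, r) + um_to_px(b, r),
               tolerance = 1e-12)
})

test_that("16-bit TIFF round trip preserves values and channel selection works", {
  tmp <- withr::local_tempdir()
  set.seed(7)
  lab <- matrix(sample(0:4000, 40 * 30, replace = TRUE), 40, 30)
  f <- file.path(tmp, "lab.tif")
  write_label_tiff(lab, f)
  expect_identical(read_label_tiff(f), lab)
  img <- read_image(f, resolution = 0.462)
  expect_s3_class(img, "raster_image")
  expect_equal(img$pixels, lab, ignore_attr = TRUE)
  expect_true(max(img$pixels) <= 65535)

  # RGB PNG: explicit channel selection equals the plane read independently
  rgb <- array(runif(20 * 20 * 3), c(20, 20, 3))
  fp <- file.path(tmp, "rgb.png")
  png::writePNG(rgb, fp)
  red <- read_image(fp, resolution = 1, channel = 1)
  ref <- round(png::readPNG(fp)[, , 1] * 255)
  expect_equal(red$pixels, ref, ignore_attr = TRUE)
  expect_error(read_image(fp, resolution = 1), "channel")
  expect_error(read_image(fp, resolution = 1, channel = 5), "out of range")
  expect_error(read_image(file.path(tmp, "nope.tif"), 1), "not found")
})

test_that("write_results emits the full consistent file set", {
  tmp <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec(width_px = 250, height_px = 250,
    resolution = 1, layout = "hexagonal", pitch_um = 50,
    boundary_width_um = 6, contrast_ratio = 2.5, rng_seed = 2))
  tab <- truth_table(ph)
  summ <- summarize_fibers(tab)
  files <- write_results(ph$truth$labels, tmp, fibers = tab, summary = summ)
  expect_true(all(file.exists(file.path(
    tmp, c("labels.tif", "fibers.csv", "summary.json",
           "feret_histogram.csv")))))
  expect_identical(read_label_tiff(file.path(tmp, "labels.tif")),
                   ph$truth$labels)
  got <- utils::read.csv(file.path(tmp, "fibers.csv"))
  expect_equal(nrow(got), nrow(tab))
  js <- jsonlite::read_json(file.path(tmp, "summary.json"))
  kept <- tab$min_feret_um[tab$excluded_reason == "none"]
  expect_equal(js$mean_min_feret_um, mean(kept), tolerance = 1e-9)
  expect_equal(js$n_kept, length(kept))
  hist_csv <- utils::read.csv(file.path(tmp, "feret_histogram.csv"))
  expect_equal(sum(hist_csv$count), length(kept))
})

test_that("write_results handles an empty fiber table", {
  tmp <- withr::local_tempdir()
  empty <- data.frame(fiber_id = integer(), csa_um2 = numeric(),
                      min_feret_um = numeric(), max_feret_um = numeric(),
                      centroid_x_px = numeric(), centroid_y_px = numeric(),
                      touches_edge = logical(),
                      excluded_reason = character())
  tab <- fiberseg:::fiber_table(empty, 0.462)
  summ <- suppressWarnings(summarize_fibers(tab))
  labels <- matrix(0L, 10, 10)
  write_results(labels, tmp, fibers = tab, summary = summ)
  got <- utils::read.csv(file.path(tmp, "fibers.csv"))
  expect_equal(nrow(got), 0L)
  js <- jsonlite::read_json(file.path(tmp, "summary.json"))
  expect_equal(js$n_kept, 0L)
})
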