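test_that("calibrated TIFF write/read recovers the pixel size with provenance", {
  d <- analytic_disk_fixture(20, um_per_px = 2.5, width = 64)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_calibrated_tiff(d$image, d$calibration, tf)
  cal <- read_pixel_size(tf)
  expect_equal(cal$s, 2.5, tolerance = 1e-12)
  # embedded physical-size XML takes precedence over resolution tags
  expect_equal(cal$source, "ome-xml")

  # resolution-tag-only file exercises the tag conversion path
  tf2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(d$image, tf2, bits.per.sample = 16L)
  coralmorph:::tiff_append_tags(tf2, xres = 10000 / 0.97, yres = 10000 / 0.97,
                                unit = "cm")
  cal2 <- read_pixel_size(tf2)
  expect_equal(cal2$source, "tiff-tag")
  # resolution tags are read back at single precision by the TIFF reader,
  # so the tag-only path is float-accurate (the embedded XML path is exact)
  expect_equal(cal2$s, 0.97, tolerance = 1e-6)

  # inch-based resolution converts through 25400 µm/inch
  tf3 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(d$image, tf3, bits.per.sample = 16L)
  coralmorph:::tiff_append_tags(tf3, xres = 25400 / 3.2, yres = 25400 / 3.2,
                                unit = "inch")
  expect_equal(read_pixel_size(tf3)$s, 3.2, tolerance = 1e-6)
})

test_that("calibration precedence is override > sidecar > embedded metadata", {
  d <- analytic_disk_fixture(10, um_per_px = 2, width = 32)
  tf <- withr::local_tempfile(fileext = ".png")
  png::writePNG(d$image, tf)
  expect_error(read_pixel_size(tf), class = "missing_calibration")

  sidecar <- sub("\\.png$", ".json", tf)
  writeLines('{"um_per_px": 1.4}', sidecar)
  withr::defer(unlink(sidecar))
  cal <- read_pixel_size(tf)
  expect_equal(cal$s, 1.4)
  expect_equal(cal$source, "sidecar")

  over <- read_pixel_size(tf, override = 9.9)
  expect_equal(over$s, 9.9)
  expect_equal(over$source, "override")
})

test_that("anisotropic or non-positive calibrations are rejected", {
  expect_error(pixel_calibration(0, "override"), class = "invalid_calibration")
  expect_error(pixel_calibration(-2, "override"), class = "invalid_calibration")
  expect_error(pixel_calibration(source = "sidecar", sx = 1.0, sy = 1.1),
               class = "anisotropic_calibration")
  # within 0.1% the mean is used
  cal <- pixel_calibration(source = "sidecar", sx = 1.0000, sy = 1.0005)
  expect_equal(cal$s, 1.00025)
})

test_that("calibration roundtrip is exact to 1e-9 relative across magnitudes", {
  img <- matrix(runif(16), 4, 4)
  for (s in c(1e-3, 0.037, 0.97, 1, 3.2, 41.7, 1e3)) {
    tf <- withr::local_tempfile(fileext = ".tif")
    write_calibrated_tiff(img, pixel_calibration(s, "override"), tf)
    expect_lt(abs(read_pixel_size(tf)$s - s) / s, 1e-9)
  }
})

test_that("mask pixel counting is exact and disk counts approach the analytic area", {
  expect_identical(mask_pixel_count(matrix(FALSE, 10, 10)), 0L)
  one <- matrix(FALSE, 10, 10); one[4, 7] <- TRUE
  expect_identical(mask_pixel_count(one), 1L)
  disk <- oracle_disk_mask(20, 64)
  expect_lt(abs(mask_pixel_count(disk) - pi * 400) / (pi * 400), 0.03)
})

test_that("physical area follows A = A_px * s^2", {
  expect_equal(physical_area(100, pixel_calibration(2, "override")), 400)
  expect_equal(physical_area(0, pixel_calibration(17, "override")), 0)
  expect_equal(physical_area(12345, pixel_calibration(0.5, "override")), 3086.25)
  expect_error(physical_area(-1, pixel_calibration(1, "override")),
               class = "invalid_argument")
})

test_that("physical area is linear in the count and quadratic in the pixel size", {
  withr::with_seed(5, {
    for (i in 1:20) {
      a <- sample(1:10000, 1); k <- sample(1:7, 1); s <- runif(1, 0.1, 10)
      c1 <- pixel_calibration(s, "override")
      c2 <- pixel_calibration(2 * s, "override")
      expect_equal(physical_area(k * a, c1), k * physical_area(a, c1))
      expect_equal(physical_area(a, c2), 4 * physical_area(a, c1))
    }
  })
})

test_that("masks round-trip through single-channel PNG", {
  m <- oracle_disk_mask(7, 24)
  tf <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, tf)
  expect_identical(read_mask_png(tf), m)
})
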