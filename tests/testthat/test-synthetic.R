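test_that("fixture generation is byte-deterministic given the seed", {
  spec <- synthetic_spec(width = 96, height = 96, tissue_radius_px = 25,
                         cup_ring_width_px = 8, seed = 123)
  a <- generate_recruit(spec)
  b <- generate_recruit(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$gt_mask, b$gt_mask)
  expect_identical(a$gt_area_um2, b$gt_area_um2)
})

test_that("harmonic-free fixtures rasterize to the analytic disk area", {
  spec <- synthetic_spec(width = 128, height = 128, tissue_radius_px = 30,
                         cup_ring_width_px = 8, harmonic_amps = numeric(0))
  fx <- generate_recruit(spec)
  expect_lt(abs(sum(fx$gt_mask) - pi * 30^2) / (pi * 30^2), 0.03)
  expect_equal(fx$gt_area_um2, sum(fx$gt_mask) * spec$um_per_px^2)
})

test_that("doubling the tissue radius quadruples the mask area", {
  for (r in c(20, 30)) {
    s1 <- synthetic_spec(width = 256, height = 256, tissue_radius_px = r,
                         cup_ring_width_px = 8, seed = 5)
    s2 <- synthetic_spec(width = 256, height = 256, tissue_radius_px = 2 * r,
                         cup_ring_width_px = 8, seed = 5)
    a1 <- sum(generate_recruit(s1)$gt_mask)
    a2 <- sum(generate_recruit(s2)$gt_mask)
    expect_lt(abs(a2 / a1 - 4), 4 * 4 / r)
  }
})

test_that("early fixtures have weaker tissue boundary contrast than late ones", {
  for (seed in c(1, 7, 99)) {
    mk <- function(stage) {
      generate_recruit(synthetic_spec(width = 96, height = 96,
                                      tissue_radius_px = 25,
                                      cup_ring_width_px = 8,
                                      stage = stage, seed = seed))
    }
    boundary_contrast <- function(fx) {
      inner <- fx$gt_mask
      ring <- !inner & (EBImage::dilate(inner * 1, EBImage::makeBrush(9, "disc")) > 0.5)
      abs(mean(fx$image[inner]) - mean(fx$image[ring]))
    }
    expect_lt(boundary_contrast(mk("early")), boundary_contrast(mk("late")))
  }
})

test_that("invalid fixture specs are rejected", {
  expect_error(synthetic_spec(width = 64, height = 64, tissue_radius_px = 40),
               class = "invalid_spec")
  expect_error(synthetic_spec(um_per_px = 0), class = "invalid_spec")
  expect_error(analytic_disk_fixture(60, width = 100), class = "invalid_spec")
})

test_that("dataset generation writes the full fixture tree with growth scaling", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(
    dir, 5, c(0, 4), growth_factor_per_week = 1.1, seed = 17,
    base_spec = synthetic_spec(width = 160, height = 160,
                               tissue_radius_px = 30, cup_ring_width_px = 8))
  expect_equal(nrow(man), 10)
  expect_length(list.files(file.path(dir, "images")), 10)
  expect_length(list.files(file.path(dir, "masks")), 10)
  expect_true(file.exists(file.path(dir, "manifest.csv")))

  med0 <- median(man$gt_area_um2[man$week == 0])
  med4 <- median(man$gt_area_um2[man$week == 4])
  # areas scale as the squared radius growth
  expect_lt(abs(med4 / med0 - (1.1^4)^2) / (1.1^4)^2, 0.05)

  dir2 <- withr::local_tempdir()
  man2 <- generate_dataset(
    dir2, 5, c(0, 4), growth_factor_per_week = 1.1, seed = 17,
    base_spec = synthetic_spec(width = 160, height = 160,
                               tissue_radius_px = 30, cup_ring_width_px = 8))
  expect_identical(man$gt_area_um2, man2$gt_area_um2)
  expect_identical(tools::md5sum(file.path(dir, "masks", basename(man$gt_mask_path))) |> unname(),
                   tools::md5sum(file.path(dir2, "masks", basename(man2$gt_mask_path))) |> unname())
})

test_that("fixture splits are disjoint, exhaustive and largest-remainder sized", {
  man <- tibble::tibble(image_id = sprintf("i%02d", 1:10), x = 1:10)
  sp <- split_fixtures(man, seed = 4)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 7L, validation = 2L, test = 1L))
  all_ids <- sort(unname(unlist(lapply(sp, `[[`, "image_id"))))
  expect_equal(all_ids, sort(man$image_id))
  expect_length(intersect(sp$train$image_id, sp$validation$image_id), 0)
  expect_length(intersect(sp$train$image_id, sp$test$image_id), 0)

  sp2 <- split_fixtures(man, seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_fixtures(man, fractions = c(0.5, 0.2, 0.2)),
               class = "invalid_argument")
})
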