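test_that("zero-jitter mock detection reproduces the ground-truth box", {
  gt <- bounding_box(20, 30, 80, 90, 128, 128)
  det <- mock_detector(gt, "early", jitter_px = 0)
  img <- matrix(0, 128, 128)
  out <- det$detect(img)
  expect_length(out, 1)
  expect_equal(out[[1]]$box, gt)
  expect_equal(out[[1]]$confidence, 0.99)
  expect_equal(out[[1]]$stage$stage, "early")
})

test_that("jittered mock detection is seed-deterministic and bounded", {
  gt <- bounding_box(20, 30, 80, 90, 128, 128)
  det <- mock_detector(gt, "late", jitter_px = 3, seed = 7)
  img <- matrix(0, 128, 128)
  b1 <- det$detect(img)[[1]]$box
  b2 <- det$detect(img)[[1]]$box
  expect_equal(b1, b2)
  for (f in c("xmin", "ymin", "xmax", "ymax")) {
    expect_lte(abs(b1[[f]] - gt[[f]]), 3)
  }
  # box in a resized frame maps back to within the jitter bound
  half <- det$detect(matrix(0, 64, 64))[[1]]$box
  back <- coralmorph:::map_box_to_frame(half, 128, 128)
  for (f in c("xmin", "ymin", "xmax", "ymax")) {
    expect_lte(abs(back[[f]] - gt[[f]]), 3 + 1e-9)
  }
})

test_that("perturbation segmenter reproduces controlled area bias on disks", {
  gt <- oracle_disk_mask(50, 128)
  img <- matrix(0, 128, 128)
  ps <- build_prompt_set(coralmorph:::mask_bounding_box(gt), "late")

  ident <- perturbation_segmenter(gt, 0)$segment(img, ps)
  expect_equal(mask_iou(ident, gt), 1)

  grown <- perturbation_segmenter(gt, +2)$segment(img, ps)
  shrunk <- perturbation_segmenter(gt, -2)$segment(img, ps)
  expect_lt(abs(sum(grown) / sum(gt) / (52 / 50)^2 - 1), 0.01)
  expect_lt(abs(sum(shrunk) / sum(gt) / (48 / 50)^2 - 1), 0.01)
})

test_that("perturbation segmenter output area is monotone in delta", {
  gt <- oracle_disk_mask(20, 64)
  img <- matrix(0, 64, 64)
  ps <- build_prompt_set(coralmorph:::mask_bounding_box(gt), "late")
  counts <- vapply(-5:5, function(d) {
    sum(perturbation_segmenter(gt, d)$segment(img, ps))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("an erosion that empties the mask is flagged, not silent", {
  gt <- oracle_disk_mask(3, 32)
  img <- matrix(0, 32, 32)
  ps <- build_prompt_set(coralmorph:::mask_bounding_box(gt), "late")
  out <- perturbation_segmenter(gt, -5)$segment(img, ps)
  expect_false(any(out))
  expect_true("empty-mask" %in% attr(out, "flags"))
})

test_that("threshold segmenter recovers a bright disk inside the prompt box", {
  d <- analytic_disk_fixture(30, width = 96)
  box <- bounding_box(16, 16, 80, 80, 96, 96)
  seg <- threshold_segmenter()
  out <- seg$segment(d$image, build_prompt_set(box, "late"))
  expect_gte(mask_iou(out, d$mask), 0.95)
})

test_that("a background point inside the only component vetoes it", {
  d <- analytic_disk_fixture(30, width = 96)
  # a box whose edge midpoints land on tissue: left midpoint is inside the disk
  box <- bounding_box(30, 16, 80, 80, 96, 96)
  ps <- build_prompt_set(box, "early")
  out <- threshold_segmenter()$segment(d$image, ps)
  expect_false(any(out))
})

test_that("contrast-free crops yield an empty low-confidence mask", {
  img <- matrix(0.5, 64, 64)
  ps <- build_prompt_set(bounding_box(10, 10, 50, 50, 64, 64), "late")
  out <- threshold_segmenter()$segment(img, ps)
  expect_false(any(out))
  expect_true(all(c("empty-mask", "low-confidence") %in% attr(out, "flags")))
})

test_that("backends never mutate the input image", {
  d <- analytic_disk_fixture(20, width = 64)
  img <- d$image
  snapshot <- img + 0
  ps <- build_prompt_set(bounding_box(8, 8, 56, 56, 64, 64), "early")
  invisible(threshold_segmenter()$segment(img, ps))
  invisible(perturbation_segmenter(d$mask, 2)$segment(img, ps))
  invisible(mock_detector(ps$box, "early", 2, seed = 1)$detect(img))
  expect_identical(img, snapshot)
})

test_that("registry dispatches factories by id and rejects unknown ids", {
  reg <- backend_registry()
  reg <- register_segmenter(reg, "s1", function(context) threshold_segmenter())
  expect_s3_class(coralmorph:::registry_segmenter(reg, "s1", list()),
                  "coral_segmenter")
  expect_error(coralmorph:::registry_segmenter(reg, "nope", list()),
               class = "configuration_error")
  expect_error(coralmorph:::registry_detector(reg, "mock", list()),
               class = "configuration_error")
})
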