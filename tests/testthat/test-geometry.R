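test_that("box centre is the exact corner midpoint", {
  expect_equal(box_center(bounding_box(0, 0, 10, 20, 10, 20)), c(x = 5, y = 10))
  expect_equal(box_center(bounding_box(2, 3, 5, 9, 10, 20)), c(x = 3.5, y = 6))
})

test_that("degenerate and out-of-frame boxes are rejected", {
  expect_error(bounding_box(7, 7, 7, 9, 20, 20), class = "invalid_geometry")
  expect_error(bounding_box(5, 9, 7, 9, 20, 20), class = "invalid_geometry")
  expect_error(bounding_box(-1, 0, 5, 5, 20, 20), class = "invalid_geometry")
  expect_error(bounding_box(0, 0, 25, 5, 20, 20), class = "invalid_geometry")
})

test_that("edge-midpoint background points come in fixed top/bottom/left/right order", {
  pts <- edge_midpoint_background_points(bounding_box(0, 0, 10, 20, 10, 20))
  coords <- t(vapply(pts, function(p) c(p$x, p$y), numeric(2)))
  expect_equal(coords, rbind(c(5, 0), c(5, 20), c(0, 10), c(10, 10)))
  expect_true(all(vapply(pts, `[[`, character(1), "label") == "background"))

  pts2 <- edge_midpoint_background_points(bounding_box(100, 40, 300, 240, 400, 300))
  coords2 <- t(vapply(pts2, function(p) c(p$x, p$y), numeric(2)))
  expect_equal(coords2, rbind(c(200, 40), c(200, 240), c(100, 140), c(300, 140)))
})

test_that("background points sit exactly on the box perimeter for random boxes", {
  withr::with_seed(11, {
    for (i in 1:100) {
      box <- random_box()
      ctr <- box_center(box)
      pts <- edge_midpoint_background_points(box)
      # exact recomputation from the centre, no tolerance
      expect_identical(pts[[1]]$x, ctr[["x"]])
      expect_identical(pts[[3]]$y, ctr[["y"]])
      on_perimeter <- vapply(pts, function(p) {
        (p$x %in% c(box$xmin, box$xmax) && p$y >= box$ymin && p$y <= box$ymax) ||
          (p$y %in% c(box$ymin, box$ymax) && p$x >= box$xmin && p$x <= box$xmax)
      }, logical(1))
      expect_true(all(on_perimeter))
    }
  })
})

test_that("prompt sets are stage-conditional: 4 background points early, none late", {
  box <- bounding_box(0, 0, 10, 20, 10, 20)
  early <- build_prompt_set(box, "early")
  late <- build_prompt_set(box, "late")
  expect_length(early$points, 4)
  expect_true(all(vapply(early$points, `[[`, character(1), "label") == "background"))
  expect_length(late$points, 0)
  # grade B resolves to early
  expect_length(build_prompt_set(box, "B")$points, 4)
  expect_length(build_prompt_set(box, stage_label(grade = "D"))$points, 0)
  expect_error(build_prompt_set(box, "mid"), class = "configuration_error")

  withr::with_seed(21, {
    for (i in 1:50) {
      box <- random_box()
      expect_length(build_prompt_set(box, "early")$points, 4)
      expect_length(build_prompt_set(box, "late")$points, 0)
    }
  })
})

test_that("prompt rescaling is per-axis affine and preserves midpoints", {
  box <- bounding_box(0, 0, 10, 20, 100, 200)
  ps <- rescale_prompt_set(build_prompt_set(box, "late"), 1024, 1024)
  expect_equal(unlist(ps$box[c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 0, ymin = 0, xmax = 102.4, ymax = 102.4))

  same <- rescale_prompt_set(build_prompt_set(box, "early"), 100, 200)
  expect_equal(same, build_prompt_set(box, "early"))

  # midpoints recomputed in the target frame match the rescaled points
  src <- build_prompt_set(bounding_box(10, 10, 30, 50, 64, 64), "early")
  dst <- rescale_prompt_set(src, 1024, 1024)
  recomputed <- edge_midpoint_background_points(dst$box)
  for (k in 1:4) {
    expect_equal(dst$points[[k]]$x, recomputed[[k]]$x)
    expect_equal(dst$points[[k]]$y, recomputed[[k]]$y)
  }

  expect_error(rescale_prompt_set(src, -5, 10), class = "invalid_argument")
})

test_that("rescale composed with its inverse is the identity within 1e-9", {
  withr::with_seed(31, {
    for (i in 1:25) {
      ps <- build_prompt_set(random_box(w = 317, h = 211), "early")
      back <- rescale_prompt_set(rescale_prompt_set(ps, 1024, 1024), 317, 211)
      expect_equal(unlist(back$box[1:4]), unlist(ps$box[1:4]), tolerance = 1e-9)
      for (k in 1:4) {
        expect_equal(back$points[[k]]$x, ps$points[[k]]$x, tolerance = 1e-9)
        expect_equal(back$points[[k]]$y, ps$points[[k]]$y, tolerance = 1e-9)
      }
    }
  })
})

test_that("prompt sets survive a JSON round trip with stable field names", {
  ps <- build_prompt_set(bounding_box(2.5, 3.25, 40, 60, 128, 96), "early")
  json <- prompt_set_to_json(ps)
  expect_match(json, '"box"'); expect_match(json, '"points"')
  expect_match(json, '"stage"'); expect_match(json, '"frame"')
  rt <- prompt_set_from_json(json)
  expect_equal(rt$box, ps$box)
  expect_equal(rt$points, ps$points)
  expect_equal(rt$stage$stage, ps$stage$stage)
})
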