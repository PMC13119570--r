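#' Detector and segmenter backend contracts
#'
#' The pipeline is agnostic to how detections and masks are produced: any
#' object with a `detect(image)` function returning a list of detections is
#' a detector, and any object with a `segment(image, prompts)` function
#' returning a logical mask in the image's frame is a segmenter. The package
#' ships deterministic reference backends (a ground-truth-derived mock
#' detector, a controlled-perturbation segmenter, and a classical
#' thresholding segmenter) that stand in for trained networks so the full
#' chain is testable at desk scale; trained-model adapters plug in through
#' the same contracts via the backend registry.
#'
#' @param detect Function `(image) -> list of detection()`.
#' @param id Backend identifier string.
#' @return `coral_detector` / `coral_segmenter` objects.
#' @name backend-contracts
NULL

#' @rdname backend-contracts
#' @export
new_detector <- function(detect, id = "detector") {
  stopifnot(is.function(detect))
  structure(list(detect = detect, id = id), class = "coral_detector")
}

#' @param segment Function `(image, prompts) -> logical matrix`.
#' @rdname backend-contracts
#' @export
new_segmenter <- function(segment, id = "segmenter") {
  stopifnot(is.function(segment))
  structure(list(segment = segment, id = id), class = "coral_segmenter")
}

#' A single detection: box, stage classification and confidence
#'
#' @param box A [bounding_box()] in the frame of the detected image.
#' @param stage A stage label (see [stage_label()]).
#' @param confidence Real in `[0, 1]`.
#' @return A `detection` object.
#' @export
detection <- function(box, stage, confidence) {
  validate_box(box)
  stage <- as_stage(stage)
  if (!is.numeric(confidence) || confidence < 0 || confidence > 1)
    cm_abort("confidence must be in [0, 1]", "invalid_argument")
  structure(list(box = box, stage = stage, confidence = as.numeric(confidence)),
            class = "detection")
}

#' Mock detector that jitters a ground-truth box
#'
#' Returns one detection whose corners are the ground-truth corners plus
#' independent uniform noise in `[-jitter_px, +jitter_px]` (original-frame
#' pixels), clamped to the frame; confidence is fixed at 0.99 and the stage
#' is the supplied ground-truth stage. Deterministic for a given `seed`.
#' When `detect()` is handed an image in a resized frame, the jittered box
#' is mapped into that frame, mirroring how a trained detector would see a
#' resized input.
#'
#' @param gt_box Ground-truth [bounding_box()] in the original frame.
#' @param stage Ground-truth stage (label, `"early"`/`"late"`, or grade).
#' @param jitter_px Non-negative corner noise half-width, pixels.
#' @param seed Optional integer seed; `detect()` re-seeds a local RNG on
#'   every call so repeated calls are identical.
#' @return A `coral_detector`.
#' @export
mock_detector <- function(gt_box, stage, jitter_px = 0, seed = NULL) {
  validate_box(gt_box)
  stage <- as_stage(stage)
  if (jitter_px < 0) cm_abort("jitter_px must be >= 0", "invalid_argument")

  draw_box <- function() {
    for (i in 1:100) {
      e <- if (jitter_px > 0) runif(4, -jitter_px, jitter_px) else rep(0, 4)
      xmin <- min(max(gt_box$xmin + e[1], 0), gt_box$image_width)
      ymin <- min(max(gt_box$ymin + e[2], 0), gt_box$image_height)
      xmax <- min(max(gt_box$xmax + e[3], 0), gt_box$image_width)
      ymax <- min(max(gt_box$ymax + e[4], 0), gt_box$image_height)
      if (xmin < xmax && ymin < ymax)
        return(bounding_box(xmin, ymin, xmax, ymax,
                            gt_box$image_width, gt_box$image_height))
    }
    cm_abort("jitter degenerated the box in 100 consecutive draws",
             "invalid_geometry")
  }

  new_detector(id = "mock", detect = function(image) {
    box <- if (is.null(seed)) draw_box() else withr::with_seed(seed, draw_box())
    h <- nrow(image); w <- ncol(image)
    list(detection(map_box_to_frame(box, w, h), stage, 0.99))
  })
}

#' Controlled-error segmenter from a ground-truth mask
#'
#' Ignores the image content and returns the ground-truth mask
#' morphologically dilated (`delta_px > 0`) or eroded (`delta_px < 0`) by
#' `round(delta_px)` pixels with a disc structuring element, emulating the
#' over-/under-segmentation regimes of real promptable segmenters with an
#' exactly known area bias. `delta_px = 0` reproduces the ground truth
#' bit-for-bit. When the image handed to `segment()` is in a different
#' (model) frame, the perturbed mask is nearest-neighbour resampled into
#' that frame.
#'
#' @param gt_mask Ground-truth logical matrix in the original frame.
#' @param delta_px Signed boundary offset in original-frame pixels.
#' @return A `coral_segmenter`. An erosion that empties the mask yields an
#'   empty mask carrying an `"empty-mask"` flag attribute.
#' @export
perturbation_segmenter <- function(gt_mask, delta_px = 0) {
  gt_mask <- as_mask(gt_mask)
  r <- round(delta_px)
  perturbed <- if (r == 0) {
    gt_mask
  } else {
    brush <- EBImage::makeBrush(2 * abs(r) + 1, "disc")
    op <- if (r > 0) EBImage::dilate else EBImage::erode
    op(gt_mask * 1, brush) > 0.5
  }
  new_segmenter(id = "perturb", segment = function(image, prompts) {
    out <- resize_nn(perturbed, nrow(image), ncol(image))
    if (!any(out)) attr(out, "flags") <- "empty-mask"
    out
  })
}

# 8-connected labelling: 4-connected pass, then union-find merge of labels
# that touch diagonally.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  h <- nrow(lab); w <- ncol(lab)
  for (shift in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(h - 1), if (shift[2] == 1) seq_len(w - 1) else 2:w]
    b <- lab[2:h, if (shift[2] == 1) 2:w else seq_len(w - 1)]
    touch <- a > 0 & b > 0 & a != b
    if (any(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, numeric(1))
  remap <- c(0, roots)[lab + 1]
  matrix(remap, h, w)
}

#' Classical thresholding segmenter
#'
#' A calibration-free baseline that honours the prompt contract: the image
#' is restricted to the prompt box, automatically thresholded (Otsu) within
#' it, any connected component containing a background prompt point is
#' vetoed, the largest surviving component is kept, and components below
#' `min_component_px` are discarded. Background-point veto is the
#' deterministic analogue of negative prompts suppressing mask expansion
#' into non-tissue regions.
#'
#' @param method Thresholding method; only `"otsu"` is implemented.
#' @param min_component_px Minimum surviving component size, pixels.
#' @return A `coral_segmenter`. Degenerate (contrast-free) crops yield an
#'   empty mask flagged `"low-confidence"`.
#' @export
threshold_segmenter <- function(method = "otsu", min_component_px = 16) {
  method <- match.arg(method)
  new_segmenter(id = "threshold", segment = function(image, prompts) {
    stopifnot(inherits(prompts, "prompt_set"))
    h <- nrow(image); w <- ncol(image)
    px <- box_pixel_range(prompts$box, h, w)
    crop <- image[px$rows, px$cols, drop = FALSE]
    empty <- matrix(FALSE, h, w)
    if (sd(crop) < 1e-3) {
      attr(empty, "flags") <- c("empty-mask", "low-confidence")
      return(empty)
    }
    thr <- EBImage::otsu(EBImage::Image(crop), range = c(0, 1))
    full <- empty
    full[px$rows, px$cols] <- crop > thr
    lab <- label_components8(full)
    for (p in prompts$points) {
      if (p$label != "background") next
      row <- min(h, max(1L, floor(p$y) + 1L))
      col <- min(w, max(1L, floor(p$x) + 1L))
      hit <- lab[row, col]
      if (hit > 0) lab[lab == hit] <- 0
    }
    sizes <- tabulate(lab[lab > 0])
    if (!length(sizes) || max(sizes) < min_component_px) {
      attr(empty, "flags") <- "empty-mask"
      return(empty)
    }
    lab == which.max(sizes)
  })
}

#' Backend registry
#'
#' Maps string ids (as referenced by a [pipeline_config()]) to backend
#' factories. A factory is a function of one argument, the per-image
#' `context` (a list with the manifest `row` and a derived integer `seed`),
#' returning a detector or segmenter; this lets ground-truth-driven mock
#' backends configure themselves per image while trained-model adapters can
#' ignore the context entirely.
#'
#' @return `backend_registry()`: an empty registry.
#' @export
backend_registry <- function() {
  structure(list(detectors = list(), segmenters = list()),
            class = "backend_registry")
}

#' @param registry A registry.
#' @param id Backend id string.
#' @param factory Function `(context) -> backend`.
#' @rdname backend_registry
#' @export
register_detector <- function(registry, id, factory) {
  stopifnot(inherits(registry, "backend_registry"), is.function(factory))
  registry$detectors[[id]] <- factory
  registry
}

#' @rdname backend_registry
#' @export
register_segmenter <- function(registry, id, factory) {
  stopifnot(inherits(registry, "backend_registry"), is.function(factory))
  registry$segmenters[[id]] <- factory
  registry
}

registry_detector <- function(registry, id, context) {
  f <- registry$detectors[[id]]
  if (is.null(f))
    cm_abort(sprintf("no detector registered under id '%s'", id),
             "configuration_error")
  f(context)
}

registry_segmenter <- function(registry, id, context) {
  f <- registry$segmenters[[id]]
  if (is.null(f))
    cm_abort(sprintf("no segmenter registered under id '%s'", id),
             "configuration_error")
  f(context)
}

# Ground truth for mock backends: box and mask from the manifest row.
context_gt_mask <- function(context) {
  path <- context$row$gt_mask_path
  if (is.null(path) || is.na(path) || !nzchar(path))
    cm_abort("manifest row lacks gt_mask_path needed by a mock backend",
             "invalid_argument")
  read_mask_png(path)
}

#' Registry preloaded with the reference backends
#'
#' Registers the `"mock"` detector (ground-truth box from the manifest's
#' mask, stage from its grade, corner jitter `jitter_px`), perturbation
#' segmenters under ids `"perturb_early"` and `"perturb_late"`, and
#' thresholding segmenters under `"threshold_early"` / `"threshold_late"`.
#' `delta_px` may be a number or a function of the per-image context
#' (e.g. to draw per-image boundary errors from `context$seed`).
#'
#' @param jitter_px Detector corner jitter, pixels.
#' @param delta_px Segmenter boundary offset, pixels, or
#'   `function(context)` returning one.
#' @param min_component_px Threshold-segmenter minimum component size.
#' @return A populated [backend_registry()].
#' @export
synthetic_registry <- function(jitter_px = 0, delta_px = 0,
                               min_component_px = 16) {
  reg <- backend_registry()
  reg <- register_detector(reg, "mock", function(context) {
    gt <- context_gt_mask(context)
    mock_detector(mask_bounding_box(gt), as_stage(context$row$grade),
                  jitter_px = jitter_px, seed = context$seed)
  })
  perturb_factory <- function(context) {
    d <- if (is.function(delta_px)) delta_px(context) else delta_px
    perturbation_segmenter(context_gt_mask(context), d)
  }
  thr_factory <- function(context) threshold_segmenter(min_component_px = min_component_px)
  reg <- register_segmenter(reg, "perturb_early", perturb_factory)
  reg <- register_segmenter(reg, "perturb_late", perturb_factory)
  reg <- register_segmenter(reg, "threshold_early", thr_factory)
  reg <- register_segmenter(reg, "threshold_late", thr_factory)
  reg
}
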