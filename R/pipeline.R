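#' Pipeline configuration
#'
#' Bundles every knob of the measure-one-image chain: which backends to use,
#' the model-frame sizes (images are resized to `detect_resize` for
#' detection and `segment_resize` for segmentation, while all geometry is
#' kept in original-frame pixels), the detection confidence floor, the
#' auto-acceptance tolerance used downstream, the mask post-processing
#' rules, and the prompt style (`"stage_conditional"`: early-stage images
#' get the four edge-midpoint background points, late-stage images the box
#' only; `"box_only"`: box-only prompts for every image, the prototype
#' behaviour; `"inverted"`: each stage gets the other stage's prompt style,
#' for stage-inversion ablations).
#'
#' @param detector_id,segmenter_id_early,segmenter_id_late Registry ids.
#' @param detect_resize,segment_resize Model frame sizes, pixels.
#' @param confidence_min Minimum detection confidence in `[0, 1]`.
#' @param aar_tolerance Auto-acceptance half-width on the area ratio.
#' @param prompts `"stage_conditional"` or `"box_only"`.
#' @param postprocess List with `largest_component`, `fill_holes`,
#'   `min_component_px`.
#' @param um_per_px_override Optional calibration override, µm/pixel.
#' @return A `pipeline_config` with a content hash in `$config_id`.
#' @export
pipeline_config <- function(detector_id = "mock",
                            segmenter_id_early = "perturb_early",
                            segmenter_id_late = "perturb_late",
                            detect_resize = 640,
                            segment_resize = 1024,
                            confidence_min = 0.25,
                            aar_tolerance = 0.05,
                            prompts = c("stage_conditional", "box_only", "inverted"),
                            postprocess = list(),
                            um_per_px_override = NULL) {
  prompts <- match.arg(prompts)
  post <- modifyList(
    list(largest_component = TRUE, fill_holes = FALSE, min_component_px = 16),
    postprocess)
  if (detect_resize <= 0 || segment_resize <= 0)
    cm_abort("resize dimensions must be positive", "configuration_error")
  if (aar_tolerance <= 0)
    cm_abort("aar_tolerance must be positive", "configuration_error")
  if (confidence_min < 0 || confidence_min > 1)
    cm_abort("confidence_min must be in [0, 1]", "configuration_error")
  cfg <- structure(
    list(detector_id = detector_id,
         segmenter_id_early = segmenter_id_early,
         segmenter_id_late = segmenter_id_late,
         detect_resize = as.integer(detect_resize),
         segment_resize = as.integer(segment_resize),
         confidence_min = confidence_min,
         aar_tolerance = aar_tolerance,
         prompts = prompts,
         postprocess = post,
         um_per_px_override = um_per_px_override),
    class = "pipeline_config")
  cfg$config_id <- config_hash(cfg)
  cfg
}

# Content hash of a config: md5 of its canonical JSON serialization.
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$config_id <- NULL
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(substr(tools::md5sum(tf), 1, 12))
}

#' Map a qualitative grade to the binary routing stage
#'
#' Pigmentation/maturity grades A-C are early-stage; D-G are late-stage.
#'
#' @param grade Single letter A-G (case-insensitive).
#' @return `"early"` or `"late"`.
#' @examples
#' stage_from_grade("B")  # early
#' stage_from_grade("F")  # late
#' @export
stage_from_grade <- function(grade) {
  g <- toupper(as.character(grade))
  if (length(g) != 1 || !g %in% LETTERS[1:7])
    cm_abort(sprintf("unknown grade '%s' (expected A-G)", grade),
             "invalid_argument")
  if (g %in% c("A", "B", "C")) "early" else "late"
}

#' Select the primary detection of a single-recruit image
#'
#' Keeps the highest-confidence detection at or above `confidence_min`;
#' ties are broken by larger box area, then by lexicographic corner order.
#' More than one above-threshold detection raises a `multi-detection` flag
#' (images are expected to contain a single recruit).
#'
#' @param dets List of [detection()]s.
#' @param confidence_min Confidence floor.
#' @return List with `detection` and logical `multi`.
#' @export
select_primary_detection <- function(dets, confidence_min = 0.25) {
  keep <- Filter(function(d) d$confidence >= confidence_min, dets)
  if (!length(keep)) {
    best <- if (length(dets)) max(vapply(dets, `[[`, numeric(1), "confidence")) else NA_real_
    cm_abort(
      sprintf("no detection at or above confidence %g (best rejected: %s)",
              confidence_min, format(best)),
      "no_detection", best_rejected = best)
  }
  ord <- order(
    -vapply(keep, `[[`, numeric(1), "confidence"),
    -vapply(keep, function(d) box_area(d$box), numeric(1)),
    vapply(keep, function(d) d$box$xmin, numeric(1)),
    vapply(keep, function(d) d$box$ymin, numeric(1)),
    vapply(keep, function(d) d$box$xmax, numeric(1)),
    vapply(keep, function(d) d$box$ymax, numeric(1)))
  list(detection = keep[[ord[1]]], multi = length(keep) > 1)
}

#' Route a detection to its stage-specific segmenter id
#'
#' @param det A [detection()] with resolved stage.
#' @param config A [pipeline_config()].
#' @return The segmenter id string for the detection's stage.
#' @export
route_stage <- function(det, config) {
  switch(det$stage$stage,
         early = config$segmenter_id_early,
         late = config$segmenter_id_late,
         cm_abort("unresolved stage", "configuration_error"))
}

#' Post-process a segmentation mask
#'
#' Optionally keeps only the largest 8-connected component that intersects
#' the detection box, fills interior holes, and discards results below the
#' minimum component size (yielding an empty, flagged mask).
#'
#' @param mask Logical matrix in the image frame.
#' @param box The detection [bounding_box()] in the same frame.
#' @param config A [pipeline_config()] (its `$postprocess` is used).
#' @return Logical matrix; degenerate results carry a `"flags"` attribute.
#' @export
postprocess_mask <- function(mask, box, config) {
  mask <- as_mask(mask)
  post <- config$postprocess
  flags <- attr(mask, "flags") %||% character(0)
  out <- mask
  if (isTRUE(post$largest_component) && any(mask)) {
    lab <- label_components8(mask)
    px <- box_pixel_range(box, nrow(mask), ncol(mask))
    in_box <- unique(as.vector(lab[px$rows, px$cols]))
    in_box <- in_box[in_box > 0]
    if (!length(in_box)) {
      out <- matrix(FALSE, nrow(mask), ncol(mask))
    } else {
      sizes <- vapply(in_box, function(l) sum(lab == l), numeric(1))
      out <- lab == in_box[which.max(sizes)]
    }
  }
  if (isTRUE(post$fill_holes) && any(out)) {
    out <- EBImage::fillHull(out * 1) > 0.5
  }
  if (sum(out) < post$min_component_px) {
    out <- matrix(FALSE, nrow(mask), ncol(mask))
  }
  if (!any(out)) flags <- union(flags, "empty-mask")
  attr(out, "flags") <- flags
  out
}

empty_record <- function(image_id, row, config_id) {
  tibble::tibble(
    image_id = image_id,
    dataset = as.character(row$dataset %||% NA),
    week = as.numeric(row$week %||% NA),
    stage = NA_character_, confidence = NA_real_,
    xmin = NA_real_, ymin = NA_real_, xmax = NA_real_, ymax = NA_real_,
    a_px = NA_integer_, um_per_px = NA_real_, area_um2 = NA_real_,
    segmenter_id = NA_character_, flags = "", config_id = config_id)
}

#' Measure one image through the full hierarchical chain
#'
#' Executes calibration lookup, detection on the `detect_resize` frame (box
#' mapped back to original pixels), primary-detection selection,
#' stage-conditional prompt construction in the original frame, prompt
#' rescaling to the `segment_resize` frame, segmentation, nearest-neighbour
#' mapping of the mask back to the original frame, post-processing, pixel
#' counting and physical-area conversion. Failures at any stage become
#' flags on the returned record (never silent drops); only an unreadable
#' image file raises an error.
#'
#' @param image_path Path to a calibrated TIFF (or PNG with sidecar).
#' @param config A [pipeline_config()].
#' @param registry A [backend_registry()] with the configured ids.
#' @param context Per-image context list (manifest `row`, integer `seed`)
#'   handed to backend factories.
#' @param keep_mask Attach the final predicted mask to the record as the
#'   `"mask"` attribute (for mask-level evaluation such as IoU).
#' @return One-row tibble (the measurement record).
#' @export
measure_image <- function(image_path, config, registry, context = list(),
                          keep_mask = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  context$row <- context$row %||% list()
  rec <- empty_record(context$row$image_id %||% basename(image_path),
                      context$row, config$config_id)
  flags <- character(0)

  calib <- tryCatch(read_pixel_size(image_path, config$um_per_px_override),
                    coralmorph_error = function(e) {
                      if (inherits(e, "missing_calibration")) NULL else stop(e)
                    })
  if (is.null(calib)) flags <- c(flags, "missing-calibration")
  else rec$um_per_px <- calib$s

  img <- read_image_gray(image_path)
  h <- nrow(img); w <- ncol(img)

  det_frame <- resize_nn(img, config$detect_resize, config$detect_resize)
  detector <- registry_detector(registry, config$detector_id, context)
  dets <- detector$detect(det_frame)
  dets <- lapply(dets, function(d) {
    d$box <- map_box_to_frame(d$box, w, h)
    d
  })

  sel <- tryCatch(select_primary_detection(dets, config$confidence_min),
                  no_detection = function(e) NULL)
  if (is.null(sel)) {
    rec$flags <- paste(c(flags, "no-detection"), collapse = ";")
    return(rec)
  }
  if (sel$multi) flags <- c(flags, "multi-detection")
  det <- sel$detection
  rec$stage <- det$stage$stage
  rec$confidence <- det$confidence
  rec[c("xmin", "ymin", "xmax", "ymax")] <-
    as.list(unlist(det$box[c("xmin", "ymin", "xmax", "ymax")]))

  # Prompt style may differ from the routing stage (box-only prototype,
  # stage-inversion ablation); routing always uses the classified stage.
  prompt_stage <- switch(config$prompts,
                         stage_conditional = det$stage$stage,
                         box_only = "late",
                         inverted = if (det$stage$stage == "early") "late" else "early")
  ps <- build_prompt_set(det$box, prompt_stage)
  seg_id <- route_stage(det, config)
  rec$segmenter_id <- seg_id
  segmenter <- registry_segmenter(registry, seg_id, context)

  ps_seg <- rescale_prompt_set(ps, config$segment_resize, config$segment_resize)
  seg_frame <- resize_nn(img, config$segment_resize, config$segment_resize)
  mask_seg <- segmenter$segment(seg_frame, ps_seg)
  seg_flags <- attr(mask_seg, "flags") %||% character(0)
  mask <- resize_nn(as_mask(mask_seg), h, w)
  attr(mask, "flags") <- seg_flags
  mask <- postprocess_mask(mask, det$box, config)
  flags <- union(c(flags, attr(mask, "flags") %||% character(0)), character(0))

  rec$a_px <- mask_pixel_count(mask)
  if (!is.null(calib)) rec$area_um2 <- physical_area(rec$a_px, calib)
  rec$flags <- paste(flags, collapse = ";")
  if (keep_mask) attr(rec, "mask") <- as_mask(mask)
  rec
}

#' Run the pipeline over a manifest of images
#'
#' @param manifest Data frame with at least `image_path`; optional columns
#'   `image_id`, `dataset`, `week`, `grade`, `gt_mask_path`, `gt_area_um2`
#'   ride along into the per-image context and output.
#' @param config A [pipeline_config()].
#' @param registry A [backend_registry()].
#' @param seed Integer root seed; each image gets a stable per-row seed
#'   derived from it, so reruns are byte-identical.
#' @param out_csv Optional path; when given, the records are written as CSV.
#' @return A `coral_run` tibble of measurement records (one per manifest
#'   row, in manifest order) with the config as attribute.
#' @export
run_batch <- function(manifest, config, registry, seed = 1, out_csv = NULL) {
  manifest <- tibble::as_tibble(manifest)
  if (!nrow(manifest))
    cm_abort("manifest is empty", "invalid_argument")
  if (!"image_path" %in% names(manifest))
    cm_abort("manifest must have an image_path column", "invalid_argument")

  records <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    row <- as.list(manifest[i, ])
    context <- list(row = row, seed = mix_seed(seed, i))
    tryCatch(
      measure_image(row$image_path, config, registry, context),
      io_error = function(e) {
        rec <- empty_record(row$image_id %||% basename(row$image_path),
                            row, config$config_id)
        rec$flags <- "read-error"
        rec
      })
  })
  records <- structure(records, class = c("coral_run", class(records)))
  attr(records, "config") <- config
  if (!is.null(out_csv)) {
    utils::write.csv(as.data.frame(records), out_csv, row.names = FALSE)
  }
  records
}

#' @export
print.coral_run <- function(x, ...) {
  flagged <- sum(nzchar(x$flags))
  cat(sprintf("<coral_run: %d record(s), %d flagged, config %s>\n",
              nrow(x), flagged, attr(x, "config")$config_id))
  NextMethod()
}

#' Tidy and summarise pipeline runs
#'
#' `tidy()` returns the per-image measurement records as a plain tibble;
#' `glance()` returns a one-row summary (image count, flagged count, total
#' and median measured area).
#'
#' @param x A `coral_run` from [run_batch()].
#' @param ... Unused.
#' @method tidy coral_run
#' @export
tidy.coral_run <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.coral_run
#' @method glance coral_run
#' @export
glance.coral_run <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_flagged = sum(nzchar(x$flags)),
    median_area_um2 = median(x$area_um2, na.rm = TRUE),
    total_area_um2 = sum(x$area_um2, na.rm = TRUE),
    config_id = attr(x, "config")$config_id)
}
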