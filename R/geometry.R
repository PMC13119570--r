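#' Axis-aligned bounding box in original-image pixel coordinates
#'
#' Boxes use a continuous coordinate system with the origin at the top-left
#' corner of the image: x increases rightward, y increases downward, and the
#' area of pixel (row 1, col 1) spans `[0,1) x [0,1)`. Corners are stored as
#' continuous values, so edge midpoints are exact and rescaling between
#' frames is a pure per-axis affine map. Coordinates always refer to the
#' original acquisition frame, never to a resized model frame.
#'
#' @param xmin,ymin,xmax,ymax Corner coordinates in pixels.
#' @param image_width,image_height Dimensions of the frame the box lives in.
#' @return A `bounding_box` object.
#' @examples
#' bounding_box(10, 20, 110, 180, image_width = 640, image_height = 480)
#' @export
bounding_box <- function(xmin, ymin, xmax, ymax, image_width, image_height) {
  box <- structure(
    list(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         xmax = as.numeric(xmax), ymax = as.numeric(ymax),
         image_width = as.numeric(image_width),
         image_height = as.numeric(image_height)),
    class = "bounding_box"
  )
  validate_box(box)
  box
}

validate_box <- function(box) {
  with(box, {
    if (!all(is.finite(c(xmin, ymin, xmax, ymax, image_width, image_height))))
      cm_abort("bounding box coordinates must be finite", "invalid_geometry")
    if (image_width <= 0 || image_height <= 0)
      cm_abort("image dimensions must be positive", "invalid_geometry")
    if (xmin >= xmax || ymin >= ymax)
      cm_abort(
        sprintf("degenerate box: [%g,%g] x [%g,%g] has no area",
                xmin, xmax, ymin, ymax),
        "invalid_geometry")
    if (xmin < 0 || ymin < 0 || xmax > image_width || ymax > image_height)
      cm_abort("box extends beyond the image frame", "invalid_geometry")
  })
  invisible(box)
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box [%g, %g] x [%g, %g] in %g x %g px frame>\n",
              x$xmin, x$xmax, x$ymin, x$ymax, x$image_width, x$image_height))
  invisible(x)
}

box_width <- function(box) box$xmax - box$xmin
box_height <- function(box) box$ymax - box$ymin
box_area <- function(box) box_width(box) * box_height(box)

#' Centre of a bounding box
#'
#' Returns `(xc, yc)` with `xc = (xmin + xmax) / 2` and
#' `yc = (ymin + ymax) / 2`, as continuous coordinates without rounding.
#'
#' @param box A [bounding_box()].
#' @return Named numeric vector `c(x =, y =)`.
#' @examples
#' box_center(bounding_box(0, 0, 10, 20, 10, 20))
#' @export
box_center <- function(box) {
  validate_box(box)
  c(x = (box$xmin + box$xmax) / 2, y = (box$ymin + box$ymax) / 2)
}

#' A labelled point prompt
#'
#' @param x,y Continuous pixel coordinates in the associated frame.
#' @param label `"foreground"` or `"background"`. Background (negative)
#'   points mark locations the segmenter must exclude from the mask.
#' @return A `point_prompt` object.
#' @export
point_prompt <- function(x, y, label = c("background", "foreground")) {
  label <- match.arg(label)
  structure(list(x = as.numeric(x), y = as.numeric(y), label = label),
            class = "point_prompt")
}

#' Background points at the bounding-box edge midpoints
#'
#' The negative-prompt construction for early-stage recruits: one background
#' point at the midpoint of each box edge, in the fixed order top, bottom,
#' left, right — `(xc, ymin)`, `(xc, ymax)`, `(xmin, yc)`, `(xmax, yc)`.
#' Every point lies exactly on the box perimeter.
#'
#' @param box A [bounding_box()].
#' @return List of 4 [point_prompt()]s, all labelled background.
#' @examples
#' edge_midpoint_background_points(bounding_box(0, 0, 10, 20, 10, 20))
#' @export
edge_midpoint_background_points <- function(box) {
  ctr <- box_center(box)
  list(
    point_prompt(ctr[["x"]], box$ymin, "background"),
    point_prompt(ctr[["x"]], box$ymax, "background"),
    point_prompt(box$xmin, ctr[["y"]], "background"),
    point_prompt(box$xmax, ctr[["y"]], "background")
  )
}

#' Developmental stage label
#'
#' Recruits carry a binary routing stage, optionally derived from a
#' qualitative pigmentation grade A-G: grades A-C are early-stage, D-G are
#' late-stage.
#'
#' @param stage `"early"` or `"late"`; may be `NULL` when `grade` is given.
#' @param grade Optional single letter in A-G.
#' @return A `stage_label` object.
#' @examples
#' stage_label(grade = "B")  # early
#' stage_label("late")
#' @export
stage_label <- function(stage = NULL, grade = NULL) {
  if (!is.null(grade)) {
    derived <- stage_from_grade(grade)
    if (!is.null(stage) && !identical(stage, derived))
      cm_abort(sprintf("stage '%s' contradicts grade '%s' (maps to '%s')",
                       stage, grade, derived), "invalid_argument")
    stage <- derived
  }
  if (is.null(stage) || !stage %in% c("early", "late"))
    cm_abort("stage must resolve to 'early' or 'late'", "configuration_error")
  structure(list(stage = stage, grade = grade), class = "stage_label")
}

as_stage <- function(x) {
  if (inherits(x, "stage_label")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (x %in% c("early", "late")) return(stage_label(x))
    if (toupper(x) %in% LETTERS[1:7]) return(stage_label(grade = toupper(x)))
  }
  cm_abort("cannot interpret stage", "configuration_error")
}

#' Stage-conditional prompt set for a promptable segmenter
#'
#' Builds the input contract for a segmenter backend from a detection box
#' and a resolved stage. Early-stage prompts consist of the box plus four
#' background points at the box-edge midpoints (to suppress mask leakage
#' into the corallite cup and substrate); late-stage prompts are the box
#' alone. No foreground points are ever used.
#'
#' @param box A [bounding_box()].
#' @param stage A [stage_label()], `"early"`/`"late"`, or a grade letter.
#' @return A `prompt_set` with fields `box`, `points`, `stage`,
#'   `frame_width`, `frame_height`.
#' @examples
#' ps <- build_prompt_set(bounding_box(0, 0, 10, 20, 10, 20), "early")
#' length(ps$points)  # 4
#' @export
build_prompt_set <- function(box, stage) {
  validate_box(box)
  stage <- as_stage(stage)
  points <- if (stage$stage == "early") edge_midpoint_background_points(box) else list()
  structure(
    list(box = box, points = points, stage = stage,
         frame_width = box$image_width, frame_height = box$image_height),
    class = "prompt_set"
  )
}

#' @export
print.prompt_set <- function(x, ...) {
  cat(sprintf("<prompt_set stage=%s, %d background point(s), frame %g x %g>\n",
              x$stage$stage, length(x$points), x$frame_width, x$frame_height))
  invisible(x)
}

#' Rescale a prompt set into another frame
#'
#' Applies the per-axis affine scaling `to_width / frame_width`,
#' `to_height / frame_height` to the box corners and every point. Labels and
#' point ordering are preserved; because the scaling is affine per axis,
#' edge midpoints map exactly onto the midpoints of the scaled box.
#'
#' @param ps A [build_prompt_set()] result.
#' @param to_width,to_height Target frame dimensions in pixels.
#' @return A `prompt_set` in the target frame.
#' @export
rescale_prompt_set <- function(ps, to_width, to_height) {
  stopifnot(inherits(ps, "prompt_set"))
  if (to_width <= 0 || to_height <= 0)
    cm_abort("target frame dimensions must be positive", "invalid_argument")
  fx <- to_width / ps$frame_width
  fy <- to_height / ps$frame_height
  box <- bounding_box(ps$box$xmin * fx, ps$box$ymin * fy,
                      ps$box$xmax * fx, ps$box$ymax * fy,
                      to_width, to_height)
  points <- lapply(ps$points, function(p) point_prompt(p$x * fx, p$y * fy, p$label))
  structure(
    list(box = box, points = points, stage = ps$stage,
         frame_width = as.numeric(to_width), frame_height = as.numeric(to_height)),
    class = "prompt_set"
  )
}

#' Serialize / deserialize a prompt set as JSON
#'
#' Stable field names:
#' `{box:{xmin,ymin,xmax,ymax}, points:[{x,y,label}], stage, frame:{w,h}}`.
#'
#' @param ps A prompt set.
#' @return `prompt_set_to_json()`: a JSON string; `prompt_set_from_json()`:
#'   a `prompt_set`.
#' @export
prompt_set_to_json <- function(ps) {
  stopifnot(inherits(ps, "prompt_set"))
  obj <- list(
    box = list(xmin = ps$box$xmin, ymin = ps$box$ymin,
               xmax = ps$box$xmax, ymax = ps$box$ymax),
    points = lapply(ps$points, function(p) list(x = p$x, y = p$y, label = p$label)),
    stage = ps$stage$stage,
    frame = list(w = ps$frame_width, h = ps$frame_height)
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' @param json JSON string produced by `prompt_set_to_json()`.
#' @rdname prompt_set_to_json
#' @export
prompt_set_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  box <- bounding_box(obj$box$xmin, obj$box$ymin, obj$box$xmax, obj$box$ymax,
                      obj$frame$w, obj$frame$h)
  ps <- build_prompt_set(box, obj$stage)
  # Round-trip any serialized points verbatim (they must match the
  # stage-conditional construction; verify rather than trust).
  ser <- lapply(obj$points, function(p) point_prompt(p$x, p$y, p$label))
  if (length(ser) != length(ps$points))
    cm_abort("serialized points inconsistent with stage", "invalid_argument")
  ps$points <- ser
  ps
}
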