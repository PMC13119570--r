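# Nearest-neighbour resampling with centre-aligned index mapping.
#
# Output pixel (i, j) (1-based) has centre ((j-0.5) * W/out_w,
# (i-0.5) * H/out_h) in source coordinates and takes the value of the source
# pixel containing that centre. Binary masks stay binary, and composing an
# upsample (target >= source) with the matching downsample is an exact
# identity, which the end-to-end identity tests rely on.
resize_nn <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  if (out_h == h && out_w == w) return(m)
  rows <- pmin(h, pmax(1L, floor((seq_len(out_h) - 0.5) * h / out_h) + 1L))
  cols <- pmin(w, pmax(1L, floor((seq_len(out_w) - 0.5) * w / out_w) + 1L))
  m[rows, cols, drop = FALSE]
}

# Rescale a bounding box between frames (continuous per-axis scaling).
map_box_to_frame <- function(box, to_width, to_height) {
  fx <- to_width / box$image_width
  fy <- to_height / box$image_height
  bounding_box(box$xmin * fx, box$ymin * fy, box$xmax * fx, box$ymax * fy,
               to_width, to_height)
}

# 1-based pixel index ranges whose centres fall inside the box.
box_pixel_range <- function(box, h, w) {
  cols <- seq.int(max(1L, ceiling(box$xmin + 0.5)), min(w, floor(box$xmax + 0.5)))
  rows <- seq.int(max(1L, ceiling(box$ymin + 0.5)), min(h, floor(box$ymax + 0.5)))
  if (!length(rows) || !length(cols) || rows[1] > rows[length(rows)] ||
      cols[1] > cols[length(cols)])
    cm_abort("box covers no pixel centres", "invalid_geometry")
  list(rows = rows, cols = cols)
}

# Tight continuous bounding box of a mask's TRUE pixels (pixel c spans
# [c-1, c) on its axis).
mask_bounding_box <- function(mask) {
  mask <- as_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) cm_abort("mask is empty; no bounding box", "invalid_geometry")
  bounding_box(min(idx[, 2]) - 1, min(idx[, 1]) - 1,
               max(idx[, 2]), max(idx[, 1]),
               ncol(mask), nrow(mask))
}
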