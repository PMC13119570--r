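#' Physical pixel calibration
#'
#' Records the physical pixel size `s` in micrometres per pixel together
#' with its provenance. When per-axis sizes are available they must agree to
#' within 0.1% relative (the area formula `A = A_px * s^2` assumes a single
#' scalar pixel size); anisotropy beyond that tolerance is an error, never
#' silently averaged.
#'
#' @param s Scalar pixel size, µm/pixel. If omitted, taken as the mean of
#'   `sx` and `sy`.
#' @param source One of `"tiff-tag"`, `"ome-xml"`, `"sidecar"`, `"override"`.
#' @param sx,sy Optional per-axis pixel sizes, µm/pixel.
#' @return A `pixel_calibration` object.
#' @examples
#' pixel_calibration(2.5, "override")
#' @export
pixel_calibration <- function(s = NULL,
                              source = c("override", "sidecar", "ome-xml", "tiff-tag"),
                              sx = NULL, sy = NULL) {
  source <- match.arg(source)
  if (!is.null(sx) && !is.null(sy)) {
    if (sx <= 0 || sy <= 0)
      cm_abort("pixel sizes must be positive", "invalid_calibration")
    if (abs(sx - sy) / mean(c(sx, sy)) > 1e-3)
      cm_abort(
        sprintf("anisotropic pixels (sx = %g, sy = %g µm/px) exceed 0.1%% tolerance",
                sx, sy),
        "anisotropic_calibration")
    s <- s %||% mean(c(sx, sy))
  }
  if (is.null(s) || !is.finite(s) || s <= 0)
    cm_abort("pixel size s must be a positive finite number (µm/px)",
             "invalid_calibration")
  structure(list(s = as.numeric(s), source = source, sx = sx, sy = sy),
            class = "pixel_calibration")
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat(sprintf("<pixel_calibration s = %g µm/px (%s)>\n", x$s, x$source))
  invisible(x)
}

sidecar_path <- function(image_path) {
  paste0(tools::file_path_sans_ext(image_path), ".json")
}

parse_physical_size_xml <- function(description) {
  # Pixel-size fields in an embedded OME-style XML block; values are in µm
  # (unit attributes of "um"/"µm" accepted, anything else rejected).
  grab <- function(attr) {
    m <- regmatches(description,
                    regexpr(paste0(attr, '="([^"]*)"'), description))
    if (!length(m)) return(NULL)
    sub(paste0(attr, '="([^"]*)"'), "\\1", m)
  }
  px <- grab("PhysicalSizeX")
  if (is.null(px)) return(NULL)
  for (u in c(grab("PhysicalSizeXUnit"), grab("PhysicalSizeYUnit"))) {
    if (!is.null(u) && !u %in% c("um", "µm"))
      cm_abort(sprintf("unsupported physical-size unit '%s'", u),
               "invalid_calibration")
  }
  py <- grab("PhysicalSizeY")
  list(sx = as.numeric(px), sy = if (is.null(py)) NULL else as.numeric(py))
}

resolution_to_um_per_px <- function(res, unit) {
  # TIFF resolution tags store pixels per unit; convert to µm per pixel.
  per_unit_um <- switch(unit, inch = 25400, cm = 10000, return(NULL))
  per_unit_um / res
}

#' Read the physical pixel size of an image
#'
#' Resolves the µm-per-pixel calibration of a microscopy image with the
#' precedence: explicit `override` > JSON sidecar (`<image>.json` with
#' `{"um_per_px": x}` or `{"um_per_px_x": x, "um_per_px_y": y}`) > embedded
#' OME-style XML physical-size fields > TIFF resolution tags (converted from
#' pixels-per-inch/cm to µm/pixel). A missing calibration is an error —
#' physical areas must never be computed from a silently assumed pixel size.
#'
#' @param image_path Path to a TIFF or PNG image.
#' @param override Optional pixel size in µm/pixel that short-circuits all
#'   metadata lookup.
#' @return A [pixel_calibration()] with provenance in `$source`.
#' @export
read_pixel_size <- function(image_path, override = NULL) {
  if (!is.null(override)) return(pixel_calibration(override, "override"))
  if (!file.exists(image_path))
    cm_abort(sprintf("image not found: %s", image_path), "io_error")

  sc <- sidecar_path(image_path)
  if (file.exists(sc)) {
    obj <- jsonlite::fromJSON(sc)
    if (!is.null(obj$um_per_px))
      return(pixel_calibration(obj$um_per_px, "sidecar"))
    if (!is.null(obj$um_per_px_x) && !is.null(obj$um_per_px_y))
      return(pixel_calibration(source = "sidecar",
                               sx = obj$um_per_px_x, sy = obj$um_per_px_y))
    cm_abort(sprintf("sidecar %s lacks um_per_px", sc), "missing_calibration")
  }

  if (tolower(tools::file_ext(image_path)) %in% c("tif", "tiff")) {
    info <- attributes(suppressWarnings(tiff::readTIFF(image_path, info = TRUE)))
    if (!is.null(info$description)) {
      ps <- parse_physical_size_xml(info$description)
      if (!is.null(ps))
        return(pixel_calibration(source = "ome-xml", sx = ps$sx,
                                 sy = ps$sy %||% ps$sx))
    }
    unit <- info$resolution.unit %||% "none"
    if (!is.null(info$x.resolution) && unit %in% c("inch", "cm")) {
      sx <- resolution_to_um_per_px(info$x.resolution, unit)
      sy <- resolution_to_um_per_px(info$y.resolution %||% info$x.resolution, unit)
      return(pixel_calibration(source = "tiff-tag", sx = sx, sy = sy))
    }
  }

  cm_abort(
    sprintf("no pixel-size calibration found for %s (no override, sidecar, OME field or resolution tag)",
            image_path),
    "missing_calibration")
}

#' Write an image as a calibrated TIFF
#'
#' Writes the raster and embeds the pixel size both as an OME-style XML
#' description (full double precision, the preferred read path) and as TIFF
#' X/YResolution tags in pixels per centimetre, so that
#' [read_pixel_size()] on the result recovers `s` to better than 1e-9
#' relative error.
#'
#' @param image Numeric matrix (grayscale) or H x W x 3 array with values
#'   in `[0, 1]`.
#' @param calib A [pixel_calibration()].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_calibrated_tiff <- function(image, calib, path) {
  if (!inherits(calib, "pixel_calibration"))
    cm_abort("calib must be a pixel_calibration", "invalid_calibration")
  if (!is.numeric(image) || any(!is.finite(image)))
    cm_abort("image must be a finite numeric array", "invalid_argument")
  ok <- tryCatch(tiff::writeTIFF(clamp01(image), path, bits.per.sample = 16L),
                 error = function(e) NA)
  if (is.na(ok))
    cm_abort(sprintf("cannot write TIFF to %s", path), "io_error")
  desc <- sprintf(
    '<OME><Image><Pixels PhysicalSizeX="%.17g" PhysicalSizeXUnit="um" PhysicalSizeY="%.17g" PhysicalSizeYUnit="um"/></Image></OME>',
    calib$s, calib$s)
  tiff_append_tags(path, description = desc,
                   xres = 10000 / calib$s, yres = 10000 / calib$s, unit = "cm")
  invisible(path)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Segmentation mask helpers
#'
#' A segmentation mask is a logical matrix with the dimensions of the image
#' it annotates; its `TRUE`-pixel count is the `A_px` of the surface-area
#' formula. Masks are serialized as single-channel 0/255 PNG.
#'
#' @param mask Logical matrix.
#' @return `mask_pixel_count()`: integer count of `TRUE` cells.
#' @examples
#' mask_pixel_count(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
#' @export
mask_pixel_count <- function(mask) {
  mask <- as_mask(mask)
  sum(mask)
}

as_mask <- function(mask) {
  if (is.matrix(mask) && is.logical(mask)) return(mask)
  if (is.matrix(mask) && is.numeric(mask)) return(mask > 0.5)
  cm_abort("mask must be a logical matrix", "invalid_argument")
}

#' @param path PNG path.
#' @rdname mask_pixel_count
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname mask_pixel_count
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Physical surface area from a mask pixel count
#'
#' The measured area is `A = A_px * s^2`: each of the `A_px` mask pixels
#' covers a physical square of side `s` µm, so the result is in µm² when
#' `s` is in µm/pixel.
#'
#' @param a_px Non-negative pixel count.
#' @param calib A [pixel_calibration()].
#' @return Area in µm².
#' @examples
#' physical_area(100, pixel_calibration(2, "override"))  # 400 µm²
#' @export
physical_area <- function(a_px, calib) {
  if (!inherits(calib, "pixel_calibration"))
    cm_abort("calib must be a pixel_calibration", "invalid_calibration")
  if (!is.numeric(a_px) || length(a_px) != 1 || !is.finite(a_px) || a_px < 0)
    cm_abort("a_px must be a single non-negative number", "invalid_argument")
  a_px * calib$s^2
}

# Read a raster (TIFF or PNG) as a grayscale matrix in [0,1].
read_image_gray <- function(path) {
  if (!file.exists(path))
    cm_abort(sprintf("image not found: %s", path), "io_error")
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    suppressWarnings(tiff::readTIFF(path))
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    cm_abort(sprintf("unsupported image format: %s", path), "io_error")
  }
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    img <- if (ch >= 3) {
      0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  unname(as.matrix(img))
}
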