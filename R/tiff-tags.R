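# Minimal TIFF IFD editor used to embed pixel-size metadata.
#
# The bundled raster writer emits baseline little-endian TIFFs without
# resolution or description tags, so calibration tags are appended here by
# rewriting the (single) IFD at the end of the file: existing entries are
# kept, XResolution (282) / YResolution (283) / ResolutionUnit (296) /
# ImageDescription (270) are inserted in ascending tag order, and the header
# IFD pointer is repointed. Only single-directory little-endian files are
# supported, which is exactly what the writer produces.

u16_raw <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))

u32_raw <- function(x) {
  x <- round(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

raw_u16 <- function(b) as.numeric(b[1]) + 256 * as.numeric(b[2])

raw_u32 <- function(b) {
  as.numeric(b[1]) + 256 * as.numeric(b[2]) +
    65536 * as.numeric(b[3]) + 16777216 * as.numeric(b[4])
}

# Best rational p/q approximation of x with p, q < 2^32, via continued
# fractions. TIFF RATIONAL fields store two uint32s.
rational_approx <- function(x) {
  stopifnot(is.finite(x), x > 0)
  lim <- 2^32 - 1
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1; r <- x
  for (i in 1:64) {
    a <- floor(r)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (h > lim || k > lim) break
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(h1 / k1 - x) <= abs(x) * 1e-14) break
    frac <- r - a
    if (frac < 1e-15) break
    r <- 1 / frac
  }
  c(num = h1, den = k1)
}

tiff_ifd_entry <- function(tag, type, count, value_field) {
  c(u16_raw(tag), u16_raw(type), u32_raw(count), value_field)
}

# Append description and resolution tags to a single-IFD little-endian TIFF.
# resolution is in pixels per `unit` ("cm" or "inch").
tiff_append_tags <- function(path, description = NULL,
                             xres = NULL, yres = NULL,
                             unit = c("cm", "inch")) {
  unit <- match.arg(unit)
  bytes <- readBin(path, "raw", n = file.size(path))
  if (!identical(as.integer(bytes[1:2]), c(0x49L, 0x49L)))
    cm_abort("only little-endian TIFF supported", "io_error")
  ifd_off <- raw_u32(bytes[5:8])
  n <- raw_u16(bytes[ifd_off + (1:2)])
  old_entries <- lapply(seq_len(n), function(i) {
    bytes[ifd_off + 2 + (i - 1) * 12 + (1:12)]
  })
  next_off <- bytes[ifd_off + 2 + n * 12 + (1:4)]

  new_tags <- integer(0)
  data_blob <- raw(0)
  blob_base <- length(bytes) + length(bytes) %% 2  # word-aligned append point
  new_entries <- list()

  add_entry <- function(tag, type, count, value_field) {
    new_entries[[length(new_entries) + 1]] <<- tiff_ifd_entry(tag, type, count, value_field)
    new_tags <<- c(new_tags, tag)
  }
  add_data <- function(raw_vec) {
    off <- blob_base + length(data_blob)
    data_blob <<- c(data_blob, raw_vec, if (length(raw_vec) %% 2) as.raw(0))
    off
  }

  if (!is.null(description)) {
    ascii <- c(charToRaw(enc2utf8(description)), as.raw(0))
    add_entry(270L, 2L, length(ascii), u32_raw(add_data(ascii)))
  }
  if (!is.null(xres)) {
    r <- rational_approx(xres)
    add_entry(282L, 5L, 1L, u32_raw(add_data(c(u32_raw(r["num"]), u32_raw(r["den"])))))
  }
  if (!is.null(yres)) {
    r <- rational_approx(yres)
    add_entry(283L, 5L, 1L, u32_raw(add_data(c(u32_raw(r["num"]), u32_raw(r["den"])))))
  }
  if (!is.null(xres) || !is.null(yres)) {
    code <- if (unit == "inch") 2L else 3L
    add_entry(296L, 3L, 1L, c(u16_raw(code), as.raw(c(0, 0))))
  }

  keep <- vapply(old_entries, function(e) !(raw_u16(e[1:2]) %in% new_tags), logical(1))
  entries <- c(old_entries[keep], new_entries)
  tags <- vapply(entries, function(e) raw_u16(e[1:2]), numeric(1))
  entries <- entries[order(tags)]

  pad <- raw(length(bytes) %% 2)
  new_ifd_off <- blob_base + length(data_blob)
  ifd <- c(u16_raw(length(entries)), unlist(entries), next_off)
  out <- c(bytes, pad, data_blob, ifd)
  out[5:8] <- u32_raw(new_ifd_off)
  writeBin(out, path)
  invisible(path)
}
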