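# Stable integer seed derived from a root seed and index keys; keeps the
# result in [0, 2^31) so it is a valid R seed, and stays exact in double
# arithmetic (intermediates < 2^53).
mix_seed <- function(...) {
  h <- 0
  for (x in c(...)) {
    h <- (h * 1000003 + (as.numeric(x) %% 2147483629 + 2147483629)) %% 2147483629
  }
  as.integer(h)
}

#' Specification of a synthetic recruit fixture
#'
#' Describes one synthetic single-recruit microscopy image: a roughly
#' circular live-tissue region (radius perturbed by low-order radial
#' harmonics), a surrounding darker corallite-ring annulus, a linear
#' illumination gradient and additive Gaussian noise. Tissue contrast is
#' stage-dependent — early-stage tissue is thin and weakly pigmented (low
#' contrast against its surroundings, default 0.15) while late-stage tissue
#' is thick and strongly pigmented (default 0.6) — which is exactly the
#' regime difference the stage-routing pipeline exists to handle.
#'
#' @param width,height Frame size, pixels.
#' @param um_per_px Pixel size, µm/pixel.
#' @param stage `"early"` or `"late"`.
#' @param tissue_radius_px Mean tissue radius, pixels (default 40 px,
#'   about a 0.64 mm recruit at the default pixel size).
#' @param harmonic_amps Radial perturbation amplitudes (fractions of the
#'   radius) for harmonics k = 2, 3, ...
#' @param cup_ring_width_px Width of the corallite annulus, pixels.
#' @param tissue_contrast Tissue-over-background intensity offset in
#'   `[0, 1]`; defaults to 0.15 (early) / 0.6 (late).
#' @param illum_gradient Peak-to-centre amplitude of the linear
#'   illumination ramp, in `[0, 1]`.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed; the fixture is fully deterministic given it.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(width = 256, height = 256, um_per_px = 8,
                           stage = c("early", "late"),
                           tissue_radius_px = 40,
                           harmonic_amps = c(0.05, 0.03),
                           cup_ring_width_px = 14,
                           tissue_contrast = NULL,
                           illum_gradient = 0.10,
                           noise_sd = 0.02,
                           seed = 1) {
  stage <- match.arg(stage)
  tissue_contrast <- tissue_contrast %||% if (stage == "early") 0.15 else 0.6
  spec <- structure(
    list(width = as.integer(width), height = as.integer(height),
         um_per_px = um_per_px, stage = stage,
         tissue_radius_px = tissue_radius_px,
         harmonic_amps = harmonic_amps,
         cup_ring_width_px = cup_ring_width_px,
         tissue_contrast = tissue_contrast,
         illum_gradient = illum_gradient,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  max_r <- spec$tissue_radius_px * (1 + sum(abs(spec$harmonic_amps)))
  if (max_r + spec$cup_ring_width_px >= min(spec$width, spec$height) / 2)
    cm_abort("tissue plus cup ring does not fit in the frame", "invalid_spec")
  if (spec$um_per_px <= 0 || spec$tissue_radius_px <= 0)
    cm_abort("pixel size and radius must be positive", "invalid_spec")
  if (spec$tissue_contrast < 0 || spec$tissue_contrast > 1 ||
      spec$illum_gradient < 0 || spec$illum_gradient > 1)
    cm_abort("contrast and gradient must lie in [0, 1]", "invalid_spec")
  invisible(spec)
}

# Pixel-centre coordinate grids for an h x w frame (matrix layout: rows = y).
pixel_grid <- function(h, w) {
  list(x = matrix(rep(seq_len(w) - 0.5, each = h), h, w),
       y = matrix(rep(seq_len(h) - 0.5, times = w), h, w))
}

#' Generate one synthetic recruit fixture
#'
#' Rasterizes the tissue region in polar form
#' `r(theta) = R * (1 + sum_k amp_k * cos(k * theta + phi_k))` (harmonic
#' phases drawn from the seeded generator) with the pixel-centre inclusion
#' rule, so the returned ground-truth mask is the exact rasterization of
#' the region the image depicts. The image adds the corallite annulus,
#' illumination gradient and noise around it.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `image` (matrix in `[0, 1]`), `gt_mask` (logical
#'   matrix), `calibration` ([pixel_calibration()]) and `gt_area_um2`.
#' @export
generate_recruit <- function(spec) {
  validate_spec(spec)
  withr::with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    g <- pixel_grid(h, w)
    cx <- w / 2; cy <- h / 2
    dx <- g$x - cx; dy <- g$y - cy
    rr <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)

    amps <- spec$harmonic_amps
    phases <- if (length(amps)) runif(length(amps), 0, 2 * pi) else numeric(0)
    r_bound <- spec$tissue_radius_px *
      (1 + Reduce(`+`, lapply(seq_along(amps), function(k) {
        amps[k] * cos((k + 1) * theta + phases[k])
      }), accumulate = FALSE) %||% 0)
    if (!length(amps)) r_bound <- spec$tissue_radius_px

    mask <- rr <= r_bound
    cup <- !mask & rr <= r_bound + spec$cup_ring_width_px

    bg_level <- 0.45
    img <- bg_level + spec$illum_gradient * (g$x / w - 0.5)
    # corallite annulus: darker than background, with seeded speckle texture
    img[cup] <- img[cup] - 0.15 + runif(sum(cup), -0.05, 0.05)
    img[mask] <- img[mask] + spec$tissue_contrast * 0.5
    img <- img + rnorm(h * w, 0, spec$noise_sd)
    img <- clamp01(img)

    calib <- pixel_calibration(spec$um_per_px, "override")
    list(image = img, gt_mask = mask, calibration = calib,
         gt_area_um2 = sum(mask) * spec$um_per_px^2)
  })
}

#' Analytic centred-disk fixture
#'
#' Exact rasterization (pixel-centre rule) of a disk of radius `radius_px`
#' centred in the frame, with a flat bright-on-dark image. Serves as the
#' closed-form oracle for the area formula and the controlled-bias tests:
#' the mask's pixel count approximates `pi * r^2` to within a boundary term
#' of order the perimeter.
#'
#' @param radius_px Disk radius, pixels.
#' @param um_per_px Pixel size.
#' @param width,height Frame size, pixels.
#' @return List with `image`, `mask`, `calibration`.
#' @export
analytic_disk_fixture <- function(radius_px, um_per_px = 1,
                                  width = ceiling(2.5 * radius_px),
                                  height = width) {
  if (2 * radius_px >= min(width, height))
    cm_abort("disk does not fit in the frame", "invalid_spec")
  g <- pixel_grid(height, width)
  mask <- (g$x - width / 2)^2 + (g$y - height / 2)^2 <= radius_px^2
  image <- matrix(0.15, height, width)
  image[mask] <- 0.85
  list(image = image, mask = mask,
       calibration = pixel_calibration(um_per_px, "override"))
}

default_stage_rule <- function(week) if (week < 8) "early" else "late"

#' Generate a time-series fixture dataset on disk
#'
#' Emulates a growth-monitoring study: `n_per_timepoint` recruits imaged at
#' each week in `timepoints`, with the tissue radius scaling geometrically
#' as `growth_factor_per_week^week` and the stage assigned by `stage_rule`.
#' Writes calibrated TIFFs under `images/`, ground-truth masks under
#' `masks/`, and a `manifest.csv` with ground-truth areas. Per-image seeds
#' are derived by stable hashing of `(seed, week, index)`, so regeneration
#' is reproducible.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_per_timepoint Images per time point.
#' @param timepoints Integer week numbers.
#' @param growth_factor_per_week Radius growth factor per week; the
#'   default 1.03 roughly doubles the radius over a 23-week series while
#'   keeping the largest recruit inside the default frame.
#' @param stage_rule Function `week -> "early"/"late"`; default: early
#'   before week 8.
#' @param base_spec Template [synthetic_spec()]; its radius is the week-0
#'   radius.
#' @param dataset Dataset label recorded in the manifest.
#' @param seed Root seed.
#' @return The manifest tibble (with `image_path`, `dataset`, `week`,
#'   `grade`, `gt_mask_path`, `gt_area_um2`, `image_id`), invisibly written
#'   to `manifest.csv`.
#' @export
generate_dataset <- function(out_dir, n_per_timepoint, timepoints,
                             growth_factor_per_week = 1.03,
                             stage_rule = default_stage_rule,
                             base_spec = synthetic_spec(),
                             dataset = "synthetic", seed = 1) {
  if (n_per_timepoint < 1) cm_abort("n_per_timepoint must be >= 1", "invalid_argument")
  if (growth_factor_per_week <= 0) cm_abort("growth factor must be positive", "invalid_argument")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)

  rows <- purrr::map_dfr(timepoints, function(week) {
    stage <- stage_rule(week)
    purrr::map_dfr(seq_len(n_per_timepoint), function(i) {
      spec <- base_spec
      spec$tissue_radius_px <- base_spec$tissue_radius_px * growth_factor_per_week^week
      spec$stage <- stage
      spec$tissue_contrast <- if (stage == "early") 0.15 else 0.6
      spec$seed <- mix_seed(seed, week, i)
      validate_spec(spec)
      fx <- generate_recruit(spec)
      image_id <- sprintf("%s_w%02d_i%03d", dataset, week, i)
      img_path <- file.path(out_dir, "images", paste0(image_id, ".tif"))
      mask_path <- file.path(out_dir, "masks", paste0(image_id, ".png"))
      if (file.exists(img_path) || file.exists(mask_path))
        cm_abort(sprintf("output path collision: %s", img_path), "io_error")
      write_calibrated_tiff(fx$image, fx$calibration, img_path)
      write_mask_png(fx$gt_mask, mask_path)
      tibble::tibble(
        image_id = image_id, image_path = img_path, dataset = dataset,
        week = week, grade = if (stage == "early") "B" else "E",
        gt_mask_path = mask_path, gt_area_um2 = fx$gt_area_um2)
    })
  })
  utils::write.csv(as.data.frame(rows), file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  rows
}

#' Split a manifest into train / validation / test subsets
#'
#' Seeded shuffle followed by contiguous slicing, with subset sizes chosen
#' by largest-remainder rounding of the fractions; the three subsets are
#' disjoint and exhaustive.
#'
#' @param manifest Data frame of fixtures.
#' @param fractions Three fractions summing to 1 (default 0.70/0.20/0.10).
#' @param seed Shuffle seed.
#' @return Named list `train`, `validation`, `test` of tibbles.
#' @export
split_fixtures <- function(manifest, fractions = c(0.70, 0.20, 0.10), seed = 1) {
  manifest <- tibble::as_tibble(manifest)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    cm_abort("fractions must be three non-negatives summing to 1",
             "invalid_argument")
  n <- nrow(manifest)
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_rem <- order(raw - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(rem)]] <- sizes[order_rem[seq_len(rem)]] + 1
  }
  perm <- withr::with_seed(seed, sample.int(n))
  bounds <- cumsum(c(0, sizes))
  out <- lapply(1:3, function(k) {
    manifest[sort(perm[seq.int(bounds[k] + 1, length.out = sizes[k])]), ]
  })
  names(out) <- c("train", "validation", "test")
  out
}
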