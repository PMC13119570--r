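#' Intersection over union of two binary masks
#'
#' `|a ∩ b| / |a ∪ b|`, the standard overlap score penalising both over-
#' and under-segmentation. Two empty masks score 1; exactly one empty mask
#' scores 0.
#'
#' @param a,b Logical matrices of identical dimensions.
#' @return Real in `[0, 1]`.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
#' mask_iou(m, m)  # 1
#' @export
mask_iou <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!identical(dim(a), dim(b)))
    cm_abort("mask dimensions differ", "invalid_argument")
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Area ratio of a prediction against ground truth
#'
#' `AR = A_pred / A_true`. 1 is perfect agreement; values above/below 1
#' indicate over-/under-estimation. Units must match (both µm² or both
#' px²).
#'
#' @param a_pred Predicted area, `>= 0`.
#' @param a_true Ground-truth area, `> 0`.
#' @return The ratio.
#' @examples
#' area_ratio(520, 500)  # 1.04
#' @export
area_ratio <- function(a_pred, a_true) {
  if (!is.numeric(a_true) || any(a_true <= 0))
    cm_abort("a_true must be positive", "invalid_argument")
  if (!is.numeric(a_pred) || any(a_pred < 0))
    cm_abort("a_pred must be non-negative", "invalid_argument")
  a_pred / a_true
}

#' Auto-acceptance rate
#'
#' The percentage of area ratios within `tolerance` of unity — by default
#' the closed interval `[0.95, 1.05]`. This is the pipeline's headline
#' quality-control statistic: accepted predictions need no manual
#' re-tracing. The interval is closed by convention; set `closed = FALSE`
#' for the strict variant (the difference has measure zero in practice).
#'
#' @param ars Numeric vector of area ratios.
#' @param tolerance Half-width of the acceptance band (default 0.05).
#' @param closed Include the interval endpoints? Default `TRUE`.
#' @return Percentage in `[0, 100]`.
#' @examples
#' aar(c(1.0, 1.04, 1.06))  # 66.67: two of three inside +/-5%
#' @export
aar <- function(ars, tolerance = 0.05, closed = TRUE) {
  if (!length(ars) || !is.numeric(ars))
    cm_abort("ars must be a non-empty numeric vector", "invalid_argument")
  if (tolerance <= 0)
    cm_abort("tolerance must be positive", "invalid_argument")
  dev <- abs(ars - 1)
  # epsilon guard so exactly-on-boundary ratios (e.g. 0.95) are inside the
  # closed interval despite binary representation of the decimals
  inside <- if (closed) dev <= tolerance + 1e-12 else dev < tolerance
  100 * mean(inside)
}

#' Location and spread of area ratios
#'
#' `median_ar()` is the stratum MAR (its deviation from 1 measures
#' systematic bias); `mean_std_ar()` returns the arithmetic mean and the
#' sample (N-1) standard deviation used for AVG±STD reporting.
#'
#' @param ars Non-empty numeric vector of area ratios.
#' @return `median_ar()`: scalar; `mean_std_ar()`: named vector
#'   `c(mean =, sd =)` (sd is 0 for a single observation).
#' @export
median_ar <- function(ars) {
  if (!length(ars)) cm_abort("ars must be non-empty", "invalid_argument")
  median(ars)
}

#' @rdname median_ar
#' @export
mean_std_ar <- function(ars) {
  if (!length(ars)) cm_abort("ars must be non-empty", "invalid_argument")
  c(mean = mean(ars), sd = if (length(ars) > 1) sd(ars) else 0)
}

#' Auto-acceptance difference between two pipeline arms
#'
#' `delta_aar(aar_new, aar_ref)` is `aar_new - aar_ref` in percentage
#' points: positive when the `new` arm auto-accepts more predictions.
#'
#' @param aar_new,aar_ref AAR percentages in `[0, 100]`.
#' @return Difference in percentage points.
#' @examples
#' delta_aar(83.33, 59.03)  # +24.30
#' @export
delta_aar <- function(aar_new, aar_ref) {
  stopifnot(all(aar_new >= 0 & aar_new <= 100), all(aar_ref >= 0 & aar_ref <= 100))
  aar_new - aar_ref
}

#' Change in absolute median-area-ratio bias between two arms
#'
#' `|MAR_ref - 1| - |MAR_new - 1|`: positive when the `new` arm sits closer
#' to unity (less systematic bias) than the reference. Comparison tables
#' differ in which arm plays the reference role — an improvement table puts
#' the baseline in `mar_ref`, while an ablation table puts the trusted
#' (final) arm in `mar_ref` so that negative values favour it; the report
#' layer selects the role assignment per table via its `convention`
#' argument.
#'
#' @param mar_ref,mar_new Median area ratios, `> 0`.
#' @return Signed bias reduction.
#' @examples
#' delta_abs_bias(1.037, 0.989)  # +0.026
#' @export
delta_abs_bias <- function(mar_ref, mar_new) {
  stopifnot(all(mar_ref > 0), all(mar_new > 0))
  abs(mar_ref - 1) - abs(mar_new - 1)
}

box_iou <- function(a, b) {
  ix <- max(0, min(a$xmax, b$xmax) - max(a$xmin, b$xmin))
  iy <- max(0, min(a$ymax, b$ymax) - max(a$ymin, b$ymin))
  inter <- ix * iy
  union <- box_area(a) + box_area(b) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Detection precision and recall at an IoU threshold
#'
#' Greedy one-to-one matching: predictions are visited in descending
#' confidence and each claims the unmatched ground-truth box of highest
#' IoU, provided that IoU reaches `iou_thresh`. Precision is
#' `TP / (TP + FP)` and recall `TP / (TP + FN)`; a vacuous denominator
#' (no predictions / no ground truth) scores 1.
#'
#' @param pred List of [detection()]s.
#' @param gt List of ground-truth [bounding_box()]es in the same frame.
#' @param iou_thresh Match threshold (default 0.5).
#' @return Named vector `c(precision =, recall =)`.
#' @export
detection_pr <- function(pred, gt, iou_thresh = 0.5) {
  np <- length(pred); ng <- length(gt)
  if (np == 0 && ng == 0) return(c(precision = 1, recall = 1))
  if (np == 0) return(c(precision = 1, recall = 0))
  if (ng == 0) return(c(precision = 0, recall = 1))
  ord <- order(-vapply(pred, `[[`, numeric(1), "confidence"))
  matched_gt <- rep(FALSE, ng)
  tp <- 0
  for (i in ord) {
    ious <- vapply(seq_len(ng), function(j) {
      if (matched_gt[j]) -1 else box_iou(pred[[i]]$box, gt[[j]])
    }, numeric(1))
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      matched_gt[j] <- TRUE
      tp <- tp + 1
    }
  }
  c(precision = tp / np, recall = tp / ng)
}
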