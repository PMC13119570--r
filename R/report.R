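#' Stratified evaluation of a measurement run against ground truth
#'
#' Joins per-image measurement records to ground-truth areas, computes the
#' per-image area ratio, and summarises each stratum (by default dataset,
#' week, stage): included count `n`, excluded count (flagged or unmeasured
#' records, which are reported but never enter the ratio statistics), AAR,
#' MAR (median area ratio), and mean±sd of the AR. When a `reference`
#' report is supplied, each stratum additionally gets
#' `delta_aar = aar - aar_ref` and
#' `delta_abs_bias = |mar_ref - 1| - |mar - 1|`; the `convention` records
#' which role the reference plays — `"improvement"` (reference is the
#' baseline arm, positive deltas favour this run) or `"inversion"`
#' (reference is the trusted final arm, negative deltas favour the
#' reference).
#'
#' @param records A [run_batch()] result or tibble with `image_id`,
#'   `area_um2`, `flags` and any stratum columns.
#' @param gt_table Tibble with `image_id`, `gt_area_um2` and optionally the
#'   stratum columns; omit (`NULL`) if `records` already carries
#'   `gt_area_um2`.
#' @param strata Character vector of stratum columns present after the
#'   join.
#' @param reference Optional reference report over the same strata.
#' @param tolerance Acceptance half-width for the AAR (default 0.05).
#' @param convention `"improvement"` or `"inversion"` (see above).
#' @return A `coral_report` tibble ordered by the strata.
#' @export
stratified_report <- function(records, gt_table = NULL,
                              strata = c("dataset", "week", "stage"),
                              reference = NULL, tolerance = 0.05,
                              convention = c("improvement", "inversion")) {
  convention <- match.arg(convention)
  records <- tibble::as_tibble(records)
  if (!is.null(gt_table)) {
    gt_table <- tibble::as_tibble(gt_table)
    keep <- c("image_id", "gt_area_um2", intersect(strata, names(gt_table)))
    gt_table <- gt_table[, keep]
    dup <- intersect(setdiff(keep, "image_id"), names(records))
    joined <- dplyr::left_join(records[, setdiff(names(records), dup)],
                               gt_table, by = "image_id")
  } else {
    joined <- records
  }
  if (!"gt_area_um2" %in% names(joined))
    cm_abort("no gt_area_um2 available to evaluate against", "invalid_argument")
  orphans <- joined$image_id[is.na(joined$gt_area_um2)]
  if (length(orphans))
    cm_abort(paste0("records without ground-truth area: ",
                    paste(head(orphans, 10), collapse = ", ")),
             "join_error")
  missing_strata <- setdiff(strata, names(joined))
  if (length(missing_strata))
    cm_abort(paste0("stratum column(s) not found: ",
                    paste(missing_strata, collapse = ", ")),
             "invalid_argument")

  joined <- dplyr::mutate(
    joined,
    excluded = nzchar(.data$flags %||% "") | is.na(.data$area_um2),
    ar = dplyr::if_else(.data$excluded, NA_real_,
                        .data$area_um2 / .data$gt_area_um2))

  report <- joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::summarise(
      n = sum(!.data$excluded),
      excluded_n = sum(.data$excluded),
      aar = if (any(!.data$excluded)) aar(.data$ar[!.data$excluded], tolerance) else NA_real_,
      mar = if (any(!.data$excluded)) median_ar(.data$ar[!.data$excluded]) else NA_real_,
      mean_ar = mean(.data$ar[!.data$excluded]),
      std_ar = if (sum(!.data$excluded) > 1) sd(.data$ar[!.data$excluded]) else 0,
      .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(strata)))

  if (!is.null(reference)) {
    report <- add_reference_deltas(report, reference, strata)
  }
  structure(report, class = c("coral_report", class(report)),
            convention = convention, tolerance = tolerance)
}

add_reference_deltas <- function(report, reference, strata) {
  ref <- tibble::as_tibble(reference)[, c(strata, "aar", "mar")]
  names(ref)[names(ref) == "aar"] <- "aar_ref"
  names(ref)[names(ref) == "mar"] <- "mar_ref"
  out <- dplyr::left_join(report, ref, by = strata)
  if (any(is.na(out$aar_ref)))
    cm_abort("reference report does not cover every stratum", "join_error")
  dplyr::mutate(out,
                delta_aar = delta_aar(.data$aar, .data$aar_ref),
                delta_abs_bias = delta_abs_bias(.data$mar_ref, .data$mar))
}

#' Compare two stratified reports (ablation / improvement tables)
#'
#' Pairs the strata of two single-run reports and computes
#' `delta_aar = aar_cmp - aar_ref` and
#' `delta_abs_bias = |mar_ref - 1| - |mar_cmp - 1|`. Under
#' `convention = "improvement"` the reference is the baseline arm and the
#' comparison the improved one, so positive deltas mean the comparison arm
#' is better; under `"inversion"` the reference is the trusted final arm
#' and the comparison the inverted (ablated) one, so negative deltas
#' confirm the reference.
#'
#' @param ref,cmp `coral_report`s (or tibbles with the strata plus `aar`,
#'   `mar`) over identical strata.
#' @param strata Stratum columns to pair on.
#' @param convention `"improvement"` or `"inversion"` (labels the roles;
#'   the arithmetic is determined by the (ref, cmp) argument order).
#' @return A `coral_comparison` tibble with both arms' AAR/MAR and the
#'   deltas.
#' @export
compare_reports <- function(ref, cmp, strata = c("dataset", "week", "stage"),
                            convention = c("improvement", "inversion")) {
  convention <- match.arg(convention)
  ref <- tibble::as_tibble(ref)[, c(strata, "aar", "mar")]
  cmp <- tibble::as_tibble(cmp)[, c(strata, "aar", "mar")]
  names(ref)[names(ref) %in% c("aar", "mar")] <- c("aar_ref", "mar_ref")
  names(cmp)[names(cmp) %in% c("aar", "mar")] <- c("aar_cmp", "mar_cmp")
  out <- dplyr::inner_join(ref, cmp, by = strata)
  if (nrow(out) != nrow(ref) || nrow(out) != nrow(cmp))
    cm_abort("reports do not cover identical strata", "join_error")
  out <- dplyr::mutate(out,
                       delta_aar = delta_aar(.data$aar_cmp, .data$aar_ref),
                       delta_abs_bias = delta_abs_bias(.data$mar_ref, .data$mar_cmp))
  structure(out, class = c("coral_comparison", class(out)),
            convention = convention)
}

#' @export
print.coral_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Render a report as an aligned text table
#'
#' @param report A `coral_report` or `coral_comparison`.
#' @return Character vector of lines.
#' @export
format_report <- function(report) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 4, format = "fg"))
  lines <- utils::capture.output(print(df, row.names = FALSE))
  c(lines, sprintf("# convention: %s", attr(report, "convention") %||% "none"))
}

#' Write a report as CSV plus aligned text
#'
#' @param report A `coral_report` or `coral_comparison`.
#' @param csv_path,txt_path Output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  if (!is.null(txt_path))
    writeLines(format_report(report), txt_path)
  invisible(report)
}

#' @rdname tidy.coral_run
#' @method tidy coral_report
#' @export
tidy.coral_report <- function(x, ...) tibble::as_tibble(unclass(x)[names(x)])

#' @rdname tidy.coral_run
#' @method glance coral_report
#' @export
glance.coral_report <- function(x, ...) {
  tibble::tibble(
    strata = nrow(x),
    n = sum(x$n),
    excluded_n = sum(x$excluded_n),
    overall_aar = sum(x$aar * x$n) / sum(x$n),
    convention = attr(x, "convention") %||% NA_character_)
}
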