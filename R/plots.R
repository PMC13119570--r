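#' Plot an evaluation report
#'
#' Auto-acceptance rate per week, coloured by stage and faceted by dataset;
#' the companion bias panel of the printed comparison tables is available
#' via `plot_ar_bias()`.
#'
#' @param object A `coral_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coral_report
#' @export
autoplot.coral_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$week), y = .data$aar,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$dataset), nrow = 1) +
    ggplot2::labs(x = "week", y = "auto-acceptance rate (%)",
                  fill = "stage") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Median-area-ratio bias per stratum
#'
#' @param report A `coral_report`.
#' @return A ggplot of MAR against week with the unity line.
#' @export
plot_ar_bias <- function(report) {
  df <- tibble::as_tibble(report)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$week), y = .data$mar,
                                   colour = .data$stage, group = .data$stage)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$dataset), nrow = 1) +
    ggplot2::labs(x = "week", y = "median area ratio") +
    ggplot2::theme_minimal()
}

#' Distribution of per-image area ratios with the acceptance band
#'
#' @param records Measurement records joined to ground truth (columns
#'   `area_um2`, `gt_area_um2`).
#' @param tolerance Acceptance half-width to shade (default 0.05).
#' @return A ggplot histogram.
#' @export
plot_ar_distribution <- function(records, tolerance = 0.05) {
  df <- tibble::as_tibble(records)
  df$ar <- df$area_um2 / df$gt_area_um2
  df <- df[is.finite(df$ar), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ar)) +
    ggplot2::annotate("rect", xmin = 1 - tolerance, xmax = 1 + tolerance,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "green4") +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "area ratio (predicted / ground truth)", y = "images") +
    ggplot2::theme_minimal()
}
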