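#' Plot Budyko curves
#'
#' ET/P (solid) and Q/P (dashed) against the aridity index, one colour per
#' plant-available-water coefficient.
#'
#' @param object A [budyko_curve_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.budyko_curves <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("et_over_p", "q_over_p"),
                            names_to = "ratio", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$phi, .data$value,
                                   colour = factor(.data$w),
                                   linetype = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = c(et_over_p = "solid", q_over_p = "dashed"),
      labels = c(et_over_p = "ET/P", q_over_p = "Q/P")) +
    ggplot2::labs(x = "PET/P", y = "fraction of P", colour = "w",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Whisker-box plot of zone statistics
#'
#' Draws the precomputed zone box statistics (min, Q0.2-Q0.8, max, mean) as
#' the customary box-and-whisker summary per climate zone.
#'
#' @param box A [zone_box_stats()] table.
#' @return A ggplot.
#' @export
plot_zone_box <- function(box) {
  ggplot2::ggplot(box, ggplot2::aes(x = .data$zone)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                           width = 0.2) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$q50, ymin = .data$q20,
                                        ymax = .data$q80),
                           width = 0.5, fill = "grey85") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), shape = 18, size = 3) +
    ggplot2::labs(x = NULL, y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Bar chart of wetland-loss bins
#'
#' @param bins A [loss_bins()] table, or a named list of them (one per
#'   scenario) for a dodged comparison.
#' @return A ggplot.
#' @export
plot_loss_bins <- function(bins) {
  if (!is.data.frame(bins))
    bins <- dplyr::bind_rows(bins, .id = "scenario")
  p <- ggplot2::ggplot(bins, ggplot2::aes(.data$bin, .data$count))
  if ("scenario" %in% names(bins))
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$scenario),
                               position = "dodge")
  else p <- p + ggplot2::geom_col()
  p + ggplot2::labs(x = "wetland loss relative to baseline", y = "cells") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
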