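#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar-and-error plot of group summaries
#'
#' Mean with or minus one SD per group for one or all summarized
#' quantities, in published-table style.
#'
#' @param summary A `stereo_group_summary` from [summarize_groups()].
#' @param quantity Optional single quantity to plot; default facets all.
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summary, quantity = NULL) {
  df <- summary
  if (!is.null(quantity)) {
    df <- df[df$quantity %in% quantity, ]
  }
  df$group <- factor(df$group, levels = unique(df$group))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey20") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.25, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "mean ± SD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (is.null(quantity) || length(quantity) > 1) {
    p <- p + ggplot2::facet_wrap(~quantity, scales = "free_y")
  }
  p
}

#' @export
autoplot.stereo_group_summary <- function(object, ...) {
  plot_group_summary(object, ...)
}

#' Plot a section-reduction report
#'
#' Volume and coefficients of error against the number of retained
#' sections, one line per specimen.
#'
#' @param report A `stereo_reduction` from [reduction_report()].
#' @return A ggplot object.
#' @export
plot_reduction <- function(report) {
  long <- report |>
    tidyr::pivot_longer(
      dplyr::all_of(c("volume_mm3", "predicted_ce", "empirical_ce")),
      names_to = "measure", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_sections, y = .data$value,
                                     colour = .data$specimen_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "number of sections", y = NULL, colour = "specimen") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stereo_reduction <- function(object, ...) {
  plot_reduction(object, ...)
}
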