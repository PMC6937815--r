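# ggplot2 displays of benchmark results.

#' Plot per-method Se/PPV performance
#'
#' Bar chart of the proportion of peptides with both Se and PPV above the
#' summary's threshold, per method and evaluation mode.
#'
#' @param object a [method_performance()] summary.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pep_method_summary <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 0.7
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$method,
                                                  -.data$prop_above),
                               y = .data$prop_above, fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = sprintf("proportion of peptides with Se, PPV > %.1f", thr),
      fill = "mode",
      title = "Design method performance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot mean Se and PPV per method
#'
#' @param summary a [method_performance()] summary.
#' @return a ggplot object.
#' @export
plot_se_ppv <- function(summary) {
  long <- summary |>
    tidyr::pivot_longer(c("mean_se", "mean_ppv"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~mode, ncol = 1) +
    ggplot2::labs(x = NULL, y = "mean value", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot qualifying peptides against peptide-epitope size difference
#'
#' @param size_table a [size_difference_analysis()] tibble.
#' @return a ggplot object.
#' @export
plot_size_difference <- function(size_table) {
  ggplot2::ggplot(size_table,
                  ggplot2::aes(x = .data$size_diff, y = .data$n_qualifying)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "|peptide length - epitope size| (aa)",
                  y = "qualifying peptides") +
    ggplot2::theme_minimal()
}
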