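#' Plot a calcium transient signal
#'
#' Draws the ratio trace; when a peak table is supplied, detected beats are
#' shaded and apexes marked.
#'
#' @param object A [ct_signal()].
#' @param peaks Optional peak tibble from [detect_peaks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ct_signal
#' @export
autoplot.ct_signal <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time [s]", y = "Fura-2 340/380 ratio",
      title = attr(object, "signal_id"),
      subtitle = paste0(attr(object, "condition"),
                        if (attr(object, "response_class") != "none") {
                          paste0(" / ", attr(object, "response_class"))
                        })
    ) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    apex <- tibble::tibble(time = peaks$max_time,
                           value = object$value[peaks$max_index])
    p <- p +
      ggplot2::geom_rect(
        data = peaks, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$start_time, xmax = .data$end_time,
                     ymin = -Inf, ymax = Inf),
        fill = "steelblue", alpha = 0.12
      ) +
      ggplot2::geom_point(data = apex, colour = "firebrick", size = 1.2)
  }
  p
}

#' Heatmap of a confusion matrix
#'
#' @param object A `ct_confusion`.
#' @param ... Unused.
#' @return A ggplot object with counts printed in the tiles.
#' @method autoplot ct_confusion
#' @export
autoplot.ct_confusion <- function(object, ...) {
  df <- tidy(object)
  df$truth <- factor(df$truth, levels = rev(rownames(object)))
  df$pred <- factor(df$pred, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 guide = "none") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = sprintf("accuracy %.1f%%", accuracy(object))) +
    ggplot2::theme_minimal()
}

#' Per-class distributions of the 12 peak variables
#'
#' @param features Feature tibble from [build_feature_table()].
#' @param group Grouping column (default `label`).
#' @return A faceted ggplot of boxplots, one panel per variable (free y
#'   scales; the variables live on very different scales).
#' @export
plot_feature_distributions <- function(features, group = "label") {
  long <- features |>
    dplyr::select(dplyr::all_of(c(group, ct_feature_names))) |>
    tidyr::pivot_longer(dplyr::all_of(ct_feature_names),
                        names_to = "variable", values_to = "value") |>
    dplyr::mutate(variable = factor(.data$variable,
                                    levels = ct_feature_names))
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[group]], y = .data$value,
                                     fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.25) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
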