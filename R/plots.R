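# ggplot2 output for records, metrics, and sweeps.

#' Plot an ECG record
#'
#' Stacked lead traces over a time window, with detected/annotated beat
#' positions marked when present.
#'
#' @param record An `ecg_record`.
#' @param from,to Time window in seconds (defaults to the first 10 s).
#' @return A ggplot object.
#' @export
plot_ecg <- function(record, from = 0, to = 10) {
  sig <- dplyr::filter(record$signal, .data$time >= from, .data$time <= to)
  long <- tidyr::pivot_longer(sig, cols = -c("sample", "time"),
                              names_to = "lead", values_to = "mV")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~lead, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)",
                  title = record$record_id) +
    ggplot2::theme_minimal()
  ann <- dplyr::filter(record$annotations,
                       .data$sample / record$sampling_rate >= from,
                       .data$sample / record$sampling_rate <= to)
  if (nrow(ann) > 0) {
    p <- p + ggplot2::geom_vline(
      data = tibble::tibble(time = ann$sample / record$sampling_rate),
      ggplot2::aes(xintercept = .data$time),
      color = "red", alpha = 0.3, linetype = "dashed"
    )
  }
  p
}

#' Confusion-matrix heatmap
#'
#' @param object A `beat_metrics` object.
#' @param ... Unused.
#' @return A ggplot heatmap of counts (log-shaded), rows true classes.
#' @export
autoplot.beat_metrics <- function(object, ...) {
  cm <- object$confusion
  df <- tidyr::expand_grid(true = rownames(cm), predicted = colnames(cm))
  df$count <- as.vector(t(cm))
  df$true <- factor(df$true, levels = rev(rownames(cm)))
  df$predicted <- factor(df$predicted, levels = colnames(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = log10(.data$count + 1))) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 guide = "none") +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("Overall accuracy %.2f%%",
                                  object$overall_accuracy)) +
    ggplot2::theme_minimal()
}

#' Accuracy-by-configuration plot for sweep tables
#'
#' Works with the output of [sweep_feature_sets()] (bar per combination) or
#' [sweep_n_trees()] (line over tree counts).
#'
#' @param sweep Tibble from a sweep function.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  if ("combination" %in% names(sweep)) {
    ggplot2::ggplot(sweep,
                    ggplot2::aes(x = stats::reorder(.data$combination,
                                                    .data$accuracy),
                                 y = .data$accuracy)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = "feature sets", y = "held-out accuracy (%)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(sweep, ggplot2::aes(x = .data$num_trees,
                                        y = .data$accuracy)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "trees per forest", y = "held-out accuracy (%)") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
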