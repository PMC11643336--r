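#' Plot methods for moveprof results
#'
#' `autoplot()` methods give the standard visual for each result type: the
#' selection-curve plot with the 95% rule marked, the pooled confusion
#' matrix of an evaluation report, and class-colored Sammon projections.
#'
#' @param object a fitted moveprof object.
#' @param labels optional label vector coloring a Sammon projection.
#' @param ... unused.
#' @return a ggplot object.
#' @name moveprof-autoplot
NULL

#' @rdname moveprof-autoplot
#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$score)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$chosen), size = 2) +
    ggplot2::geom_hline(
      yintercept = object$threshold * object$reference_score,
      linetype = "dashed", color = "firebrick"
    ) +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dotted") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "firebrick"),
                                guide = "none") +
    ggplot2::labs(
      x = "number of top-ranked features",
      y = "micro F1",
      title = sprintf("Feature-count selection (chosen k = %d)",
                      object$chosen_k)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname moveprof-autoplot
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  plot_confusion(object$confusion)
}

#' Confusion-matrix heatmap
#'
#' @param cm a confusion matrix (rows = truth).
#' @return a ggplot object.
#' @export
plot_confusion <- function(cm) {
  df <- as.data.frame(cm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::labs(x = "predicted", y = "true", fill = "count") +
    ggplot2::theme_minimal()
}

#' @rdname moveprof-autoplot
#' @method autoplot sammon_projection
#' @export
autoplot.sammon_projection <- function(object, labels = NULL, ...) {
  df <- tidy(object)
  df$label <- if (is.null(labels)) "all" else as.character(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                        color = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "Sammon dimension 1", y = "Sammon dimension 2",
      title = sprintf("Sammon projection (stress %.4f)", object$stress),
      color = NULL
    ) +
    ggplot2::theme_minimal()
  if (is.null(labels)) p + ggplot2::guides(color = "none") else p
}

#' Velocity envelope with detected pauses
#'
#' Diagnostic plot for segmentation: the envelope, the threshold, and the
#' detected pause intervals.
#'
#' @param envelope numeric envelope.
#' @param pauses pause table from [detect_pauses()].
#' @param rate_hz envelope rate.
#' @param threshold_dps threshold used.
#' @return a ggplot object.
#' @export
plot_segmentation <- function(envelope, pauses, rate_hz,
                              threshold_dps = 10) {
  df <- tibble::tibble(t_s = (seq_along(envelope) - 1) / rate_hz,
                       envelope = envelope)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$envelope)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::geom_hline(yintercept = threshold_dps, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "angular velocity (deg/s)") +
    ggplot2::theme_minimal()
  if (nrow(pauses) > 0) {
    p <- p + ggplot2::annotate(
      "rect", xmin = pauses$start_s, xmax = pauses$end_s,
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "steelblue"
    )
  }
  p
}
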