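# ggplot2 views of scenes, detections and reports.

#' Plot a pod annotation
#'
#' Seeds coloured by pod, joined base-to-tip, with the basal seed drawn
#' larger. The y axis is reversed to match image coordinates.
#'
#' @param object A [pod_annotation()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pod_annotation
#' @export
autoplot.pod_annotation <- function(object, ...) {
  s <- object$seeds
  ggplot2::ggplot(s, ggplot2::aes(.data$x, .data$y,
                                  group = factor(.data$pod_id),
                                  colour = factor(.data$pod_id))) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(size = .data$seed_index == 1),
                        show.legend = FALSE) +
    ggplot2::scale_size_manual(values = c(`TRUE` = 2.5, `FALSE` = 1.5)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(xlim = c(0, object$width),
                         ylim = c(object$height, 0)) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(title = object$image_id, x = "x (px)", y = "y (px)")
}

#' Plot detections over an image raster
#'
#' @param image Height x width matrix in `[0, 1]` (e.g. from
#'   [generate_scene()]), or `NULL` for detections alone.
#' @param dets Detections tibble.
#' @return A ggplot.
#' @export
plot_detections <- function(dets, image = NULL) {
  dets <- as_detections(dets)
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    rast <- tidyr::expand_grid(y = seq_len(nrow(image)) - 0.5,
                               x = seq_len(ncol(image)) - 0.5)
    rast$value <- as.vector(t(image))
    p <- p + ggplot2::geom_raster(
      data = rast, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   guide = "none")
  }
  p +
    ggplot2::geom_path(
      data = dets,
      ggplot2::aes(.data$x, .data$y, group = factor(.data$pod_id)),
      colour = "red", linewidth = 0.4) +
    ggplot2::geom_point(
      data = dets,
      ggplot2::aes(.data$x, .data$y, colour = factor(.data$seed_index)),
      size = 1.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(colour = "seed", x = "x (px)", y = "y (px)")
}

#' Precision-recall curve of an AP report
#'
#' @param object An `ap_report` from [average_precision()].
#' @param ... Unused.
#' @return A ggplot of the PR curve at OKS threshold 0.50.
#' @method autoplot ap_report
#' @export
autoplot.ap_report <- function(object, ...) {
  ggplot2::ggplot(object$pr_curve,
                  ggplot2::aes(.data$recall, .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("AP %.3f | AP50 %.3f", object$ap, object$ap50),
      x = "recall", y = "precision")
}

#' Training-loss curves of a toy model
#'
#' @param object A `pod_model` from [train_toy()].
#' @param ... Unused.
#' @return A ggplot of per-epoch loss components.
#' @method autoplot pod_model
#' @export
autoplot.pod_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$epoch, .data$value,
                               colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)")
}
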