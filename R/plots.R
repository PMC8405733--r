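# ggplot2 visualisation helpers.

#' Plot a scene with its annotations
#'
#' Grayscale image with the mask outline region shaded and click points
#' overlaid.
#'
#' @param s an [scene()].
#' @param show_mask overlay the ground-truth mask when present.
#' @return a ggplot object.
#' @export
plot_scene <- function(s, show_mask = TRUE) {
  H <- dim(s$image)[1]; W <- dim(s$image)[2]
  df <- data.frame(
    row = rep(seq_len(H), times = W),
    col = rep(seq_len(W), each = H),
    value = as.vector(s$image[, , 1L])
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = s$id, fill = "intensity") +
    ggplot2::theme_minimal()
  if (show_mask && !is.null(s$mask) && any(s$mask == 1L)) {
    md <- df[as.vector(s$mask) == 1L, ]
    p <- p + ggplot2::geom_raster(data = md, fill = "orange", alpha = 0.25)
  }
  if (nrow(s$points) > 0L) {
    pd <- data.frame(row = s$points[, 1], col = s$points[, 2])
    p <- p + ggplot2::geom_point(data = pd, colour = "red", size = 2)
  }
  p
}

#' Training-curve plot for a fit
#'
#' Validation score per epoch, one line per learning rate.
#'
#' @param object an `alcfcn_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.alcfcn_fit <- function(object, ...) {
  df <- as.data.frame(object$log)
  df$lr <- factor(format(df$lr, scientific = TRUE))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$val_score,
                                   colour = .data$lr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = paste0("validation score (", df$val_metric[1], ")"),
                  colour = "learning rate", title = object$method) +
    ggplot2::theme_minimal()
}

#' Bar plot of a metric report
#' @param object an `alcfcn_metrics`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.alcfcn_metrics <- function(object, ...) {
  df <- as.data.frame(tidy(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
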