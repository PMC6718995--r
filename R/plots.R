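#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_raster
#'   labs scale_fill_gradient coord_fixed theme_minimal autoplot
NULL

#' Plot a training history
#'
#' Training loss and validation accuracy per epoch.
#'
#' @param model A trained `dual_cnn` (or its history tibble).
#' @return A ggplot object.
#' @export
plot_training_history <- function(model) {
  h <- if (inherits(model, "dual_cnn")) model$history else model
  long <- tidyr::pivot_longer(h[, c("epoch", "train_loss", "val_accuracy")],
                              -"epoch", names_to = "metric")
  ggplot(long, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    labs(x = "epoch", y = NULL) +
    theme_minimal()
}

#' @rdname plot_training_history
#' @param object,... Passed from the `autoplot()` generic.
#' @export
autoplot.dual_cnn <- function(object, ...) plot_training_history(object)

#' Plot a 3-D activation embedding
#'
#' The first two embedding axes, with the third mapped to point size and
#' points colored by class.
#'
#' @param embedding Tibble from [embed_3d()].
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding) {
  ggplot(embedding, aes(x = .data$x, y = .data$y,
                        color = factor(.data$label), size = .data$z)) +
    geom_point(alpha = 0.8) +
    labs(color = "class", size = "z") +
    theme_minimal()
}

#' Plot a class distribution
#'
#' @param dist Tibble from [class_distribution()].
#' @return A ggplot object.
#' @export
plot_class_distribution <- function(dist) {
  ggplot(dist, aes(x = factor(.data$class), y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = "class", y = "images") +
    theme_minimal()
}

#' Plot an encoded five-zone image
#'
#' @param img Integer matrix from [encode_specimen()].
#' @return A ggplot object.
#' @export
plot_zone_image <- function(img) {
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- img[cbind(df$row, df$col)]
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    coord_fixed() +
    labs(x = NULL, y = NULL, fill = "gray") +
    theme_minimal()
}
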