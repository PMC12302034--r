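# ggplot2 helpers for training histories, embeddings and heatmaps.

#' Plot the training history of a fit
#'
#' Loss components on a log scale over epochs, with accuracy in a second
#' facet.
#'
#' @param fit An `ofml_fit`.
#' @param components Optional character vector of history columns to show.
#' @return A ggplot object.
#' @export
plot_history <- function(fit, components = NULL) {
  long <- tidy(fit)
  if (nrow(long) == 0L) stop("empty history: the fit ran for 0 epochs")
  if (is.null(components)) {
    components <- intersect(c("L_f", "L1", "L2", "L_ensemble", "L_EPKT",
                              "L_fusion_ce", "train_accuracy", "eval_accuracy"),
                            unique(long$component))
  }
  long <- long[long$component %in% components, ]
  long$kind <- ifelse(grepl("accuracy", long$component), "accuracy", "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2-D feature embedding
#'
#' @param embedding Tibble from [embed_features_2d()].
#' @param class_names Optional class names for the legend.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, class_names = NULL) {
  e <- embedding
  e$class <- if (is.null(class_names)) factor(e$label) else
    factor(class_names[e$label + 1L], levels = class_names)
  ggplot2::ggplot(e, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay a Grad-CAM heatmap on its image
#'
#' @param image `(H, W, 3)` image. @param cam `(H, W)` heatmap in `[0, 1]`
#'   from [grad_cam()]. @param alpha Heatmap opacity.
#' @return A ggplot object.
#' @export
plot_cam <- function(image, cam, alpha = 0.5) {
  H <- dim(image)[1]; W <- dim(image)[2]
  df <- expand.grid(row = seq_len(H), col = seq_len(W))
  df$cam <- as.vector(cam)
  df$grey <- as.vector((image[, , 1] + image[, , 2] + image[, , 3]) / 3)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$grey)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_raster(ggplot2::aes(alpha = .data$cam), fill = "red") +
    ggplot2::scale_alpha(range = c(0, alpha), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
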