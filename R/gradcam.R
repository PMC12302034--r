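# Grad-CAM: channel-weighted, rectified activation heatmaps at a tapped
# feature map, using spatially averaged gradients of a class score.

#' Grad-CAM heatmap for one image
#'
#' Backpropagates the chosen class's fusion-classifier score (or final
#' score, for models without a fusion head) to a tapped feature map, weights
#' each channel by its spatially averaged gradient, rectifies the weighted
#' sum, min-max normalizes, and bilinearly upsamples to the input size.
#'
#' @param fit An `ofml_fit` or `ofml_model`.
#' @param image A single `(H, W, 3)` image.
#' @param target_class 0-based class whose score is explained; default the
#'   predicted class.
#' @param tap `"cnn"`, `"mvt"` or `"fusion-input"` (mean of the two maps'
#'   heatmaps).
#' @return `(H, W)` matrix in `[0, 1]`.
#' @export
grad_cam <- function(fit, image, target_class = NULL,
                     tap = c("cnn", "mvt", "fusion-input")) {
  tap <- match.arg(tap)
  model <- if (inherits(fit, "ofml_fit")) fit$model else fit
  x <- as_image_batch(image)
  stopifnot(dim(x)[1] == 1L)
  M <- model$cfg$num_classes
  if (is.null(target_class)) {
    target_class <- predict.ofml_model(model, x)$labels[1L]
  }
  if (target_class < 0L || target_class >= M) {
    stop("target_class out of range [0, ", M, ")")
  }
  if (tap == "cnn" && !model$flags$use_cnn) stop("model has no cnn branch")
  if (tap == "mvt" && !model$flags$use_mvt) stop("model has no transformer branch")
  if (tap == "fusion-input" && !(model$flags$use_cnn && model$flags$use_mvt)) {
    stop("fusion-input tap needs both branches")
  }
  # one graph containing logits of every head plus both tapped feature maps
  x <- normalize_input(model, x)
  fwd <- list(fm1 = NULL, fm2 = NULL)
  z1 <- z2 <- zf <- NULL
  if (model$flags$use_cnn) {
    out1 <- resnet_fwd(model$cnn, x, training = FALSE)
    z1 <- out1$logits
    fwd$fm1 <- out1$taps[[model$cfg$cnn$tap_stage]]
  }
  if (model$flags$use_mvt) {
    out2 <- mvt_fwd(model$mvt, x)
    z2 <- out2$logits
    fwd$fm2 <- out2$taps[[as.character(model$mvt$tap_layer)]]
  }
  if (model$flags$use_afc) zf <- fusion_fwd(model$fusion, fwd$fm1, fwd$fm2)
  score_logits <- if (!is.null(zf)) zf else
    if (!is.null(z1) && !is.null(z2)) ag_scale(ag_add(z1, z2), 0.5) else
    if (!is.null(z1)) z1 else z2
  onehot <- matrix(0, 1L, M)
  onehot[1L, target_class + 1L] <- 1
  ag_backward(ag_sum(ag_cmul(score_logits, onehot)))
  on.exit(zero_grads(collect_params(unclass(model)[c("cnn", "mvt", "fusion")])))
  size <- dim(x)[2:3]
  cam_of <- function(fm) {
    if (is.null(fm$grad)) {
      return(matrix(0, size[1], size[2]))
    }
    cam_from_activation(fm$value[1L, , , ], fm$grad[1L, , , ], out_size = size)
  }
  out <- switch(tap,
    cnn = cam_of(fwd$fm1),
    mvt = cam_of(fwd$fm2),
    `fusion-input` = (cam_of(fwd$fm1) + cam_of(fwd$fm2)) / 2)
  out
}

#' Heatmap from an activation and its gradient
#'
#' The Grad-CAM reduction: channel weights are the spatial means of the
#' gradient; the heatmap is the rectified channel-weighted activation sum,
#' min-max normalized to `[0, 1]` and optionally bilinearly resized.
#'
#' @param activation `(h, w, c)` activation array.
#' @param gradient `(h, w, c)` gradient array.
#' @param out_size Optional `c(H, W)` output size.
#' @return `(h, w)` or `(H, W)` matrix in `[0, 1]`.
#' @export
cam_from_activation <- function(activation, gradient, out_size = NULL) {
  stopifnot(identical(dim(activation), dim(gradient)))
  w <- apply(gradient, 3L, mean)
  cam <- matrix(0, dim(activation)[1], dim(activation)[2])
  for (ch in seq_along(w)) cam <- cam + w[ch] * activation[, , ch]
  cam <- pmax(cam, 0)
  if (!is.null(out_size)) {
    cam <- resize_bilinear(cam, out_size[1], out_size[2])
  }
  rng <- range(cam)
  if (rng[2] > rng[1]) (cam - rng[1]) / (rng[2] - rng[1]) else cam * 0
}

# bilinear resize of a matrix (EBImage operates x-first, hence the flips)
resize_bilinear <- function(m, h, w) {
  t(EBImage::imageData(EBImage::resize(EBImage::Image(t(m)), w = w, h = h)))
}
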