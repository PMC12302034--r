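# 2-D embedding of fused deep features for visual inspection of class
# structure. The nonlinear mapping is delegated to a standard
# implementation (Sammon mapping, MASS); it is deterministic given its
# classical-scaling initialization, so a fixed seed yields a fixed table.

#' Embed per-sample feature vectors in two dimensions
#'
#' @param features N x d numeric matrix (e.g. [model_features()] output).
#' @param labels Length-N 0-based class labels carried into the output.
#' @param seed Seed (kept for interface stability; the mapping itself is
#'   deterministic).
#' @return Tibble with columns `x`, `y`, `label`.
#' @export
embed_features_2d <- function(features, labels, seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) < 5L) stop("need at least 5 samples to embed")
  if (length(labels) != nrow(features)) stop("label length mismatch")
  d <- stats::dist(features)
  if (max(d) == 0) {
    stop("degenerate input: all feature vectors are identical (constant features)")
  }
  # Sammon mapping needs strictly positive dissimilarities between distinct
  # points; exact duplicates are nudged by a fixed fraction of the smallest
  # positive distance.
  dmin <- min(d[d > 0])
  d[d == 0] <- dmin * 1e-6
  out <- with_seed(seed, MASS::sammon(d, k = 2L, trace = FALSE))
  tibble::tibble(x = out$points[, 1L], y = out$points[, 2L],
                 label = as.integer(labels))
}

#' Fused feature vectors of a fitted model
#'
#' The fusion classifier's input representation: both tapped feature maps
#' adaptively average-pooled to 1x1 and concatenated, one `(c1 + c2)`-vector
#' per sample.
#'
#' @param fit An `ofml_fit` or `ofml_model` with both branches.
#' @param data Images as in [predict.ofml_model()].
#' @return N x (c1 + c2) matrix.
#' @export
model_features <- function(fit, data) {
  model <- if (inherits(fit, "ofml_fit")) fit$model else fit
  if (!(model$flags$use_cnn && model$flags$use_mvt)) {
    stop("fused features need both branches")
  }
  x <- normalize_input(model, as_image_batch(data))
  with_no_grad({
    out1 <- resnet_fwd(model$cnn, x, training = FALSE)
    out2 <- mvt_fwd(model$mvt, x)
    fm1 <- out1$taps[[model$cfg$cnn$tap_stage]]
    fm2 <- out2$taps[[as.character(model$mvt$tap_layer)]]
    cbind(val(ag_gap2d(fm1)), val(ag_gap2d(fm2)))
  })
}
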