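# Ensemble classifier (mean of branch logits) and adaptive fusion classifier
# (adaptive average pooling of two intermediate feature maps to 1x1,
# channel concatenation, pointwise convolution to C channels). On 1x1 pooled
# maps the pointwise convolution is exactly a linear map with
# (c1 + c2) * C weights + C biases, so the head adds no large tunable block
# and adapts to any two input spatial sizes.

#' Ensemble classifier logits
#'
#' Element-wise arithmetic mean of the two branch logit vectors,
#' `A_e = (A_1 + A_2) / 2`. Accepts vectors or row-per-sample matrices.
#'
#' @param A1,A2 Numeric vectors (or equal-shape matrices) of branch logits.
#' @return The element-wise mean, same shape as the inputs.
#' @export
ensemble_logits <- function(A1, A2) {
  if (length(A1) != length(A2)) stop("ensemble_logits: length mismatch")
  (A1 + A2) / 2
}

make_fusion_head <- function(c1, c2, num_classes) {
  list(lin = lin_init(c1 + c2, num_classes, sd = sqrt(1 / (c1 + c2))),
       c1 = as.integer(c1), c2 = as.integer(c2),
       num_classes = as.integer(num_classes))
}

fusion_fwd <- function(head, fm1, fm2) {
  linear_fwd(ag_concat_cols(ag_gap2d(fm1), ag_gap2d(fm2)), head$lin)
}

#' Adaptive fusion classifier over two feature maps
#'
#' Pools each feature map to 1x1 by adaptive average pooling, concatenates
#' the channels (c1 + c2 total), and applies a pointwise convolution mapping
#' to `C` output channels (the number of classes). Works for any spatial
#' sizes of either map.
#'
#' @param fm1,fm2 Single-sample feature maps as `(channels, height, width)`
#'   arrays, or batches `(N, height, width, channels)`.
#' @param C Number of output channels / classes.
#' @param W Optional `(c1 + c2) x C` weight matrix (random if omitted).
#' @param b Optional length-`C` bias (zeros if omitted).
#' @return Length-`C` logits vector (or `N x C` matrix for batch input) with
#'   the pooled `(c1 + c2)`-vector(s) in `attr(, "pooled")`.
#' @export
fusion_forward <- function(fm1, fm2, C, W = NULL, b = NULL) {
  p1 <- pool_channels(fm1)
  p2 <- pool_channels(fm2)
  if (nrow(p1) != nrow(p2)) stop("fusion_forward: batch sizes differ")
  pooled <- cbind(p1, p2)
  cc <- ncol(pooled)
  if (is.null(W)) W <- matrix(stats::rnorm(cc * C, 0, sqrt(1 / cc)), cc, C)
  if (is.null(b)) b <- numeric(C)
  stopifnot(nrow(W) == cc, ncol(W) == C, length(b) == C)
  out <- sweep(pooled %*% W, 2L, b, "+")
  if (nrow(out) == 1L) {
    out <- drop(out)
    pooled <- drop(pooled)
  }
  structure(out, pooled = pooled)
}

# adaptive average pooling to 1x1; accepts (C,h,w) single sample or
# (N,h,w,C) batch, returns (N, C)
pool_channels <- function(fm) {
  d <- dim(fm)
  if (length(d) == 3L) {
    # channels-first single sample
    matrix(apply(fm, 1L, mean), 1L)
  } else if (length(d) == 4L) {
    val(ag_gap2d(ag_node(fm)))
  } else {
    stop("feature map must be a 3-D or 4-D array")
  }
}

#' Parameter count of the fusion head
#'
#' `(c1 + c2) * C + C`: pointwise-convolution weights plus biases.
#'
#' @param c1,c2 Channel counts of the two feature maps. @param C Classes.
#' @return Integer parameter count.
#' @export
fusion_param_count <- function(c1, c2, C) {
  as.integer((c1 + c2) * C + C)
}
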