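# Residual convolutional branch (bottleneck ResNet, ResNet-50 layout by
# default) producing class logits and tappable intermediate feature maps.
#
# Tap points follow the "conv layer" numbering used for the fusion-classifier
# ablations, anchored by printed shape rather than by stage name:
#   tap 1: stem + max-pool output      (base channels,      size/4)
#   tap 2: first residual stage output (4*base channels,    size/4)
#   tap 3: second residual stage output(8*base channels,    size/8)
# With base = 64 and 224-px input, tap 3 is (512, 28, 28) — the default
# intermediate feature handed to the fusion classifier.

make_resnet <- function(num_classes, base = 64L, blocks = c(3L, 4L, 6L, 3L),
                        in_channels = 3L) {
  stem <- list(conv = conv_init(7L, in_channels, base), bn = bn_init(base))
  stages <- list()
  cin <- base
  for (i in seq_along(blocks)) {
    width <- base * 2L^(i - 1L)
    cout <- width * 4L
    stage <- list()
    for (j in seq_len(blocks[i])) {
      stride <- if (i > 1L && j == 1L) 2L else 1L
      stage[[j]] <- list(
        c1 = conv_init(1L, cin, width), b1 = bn_init(width),
        c2 = conv_init(3L, width, width), b2 = bn_init(width),
        c3 = conv_init(1L, width, cout), b3 = bn_init(cout),
        stride = stride,
        down = if (stride != 1L || cin != cout) {
          list(conv = conv_init(1L, cin, cout), bn = bn_init(cout))
        } else NULL)
      cin <- cout
    }
    stages[[i]] <- stage
  }
  structure(list(stem = stem, stages = stages,
                 head = lin_init(cin, num_classes, sd = sqrt(1 / cin)),
                 base = as.integer(base), blocks = as.integer(blocks),
                 num_classes = as.integer(num_classes)),
            class = "resnet_branch")
}

bottleneck_fwd <- function(x, blk, training) {
  h <- ag_relu(bn_fwd(conv_fwd(x, blk$c1, 1L, 0L), blk$b1, training))
  h <- ag_relu(bn_fwd(conv_fwd(h, blk$c2, blk$stride, 1L), blk$b2, training))
  h <- bn_fwd(conv_fwd(h, blk$c3, 1L, 0L), blk$b3, training)
  idn <- if (is.null(blk$down)) x else {
    bn_fwd(conv_fwd(x, blk$down$conv, blk$stride, 0L), blk$down$bn, training)
  }
  ag_relu(ag_add(h, idn))
}

# Forward pass; returns nodes for the logits and the three tap points.
resnet_fwd <- function(model, x, training = FALSE) {
  x <- as_node(x)
  h <- ag_relu(bn_fwd(conv_fwd(x, model$stem$conv, 2L, 3L), model$stem$bn, training))
  h <- ag_maxpool2d(h, 3L, 2L, 1L)
  taps <- list(h)
  for (i in seq_along(model$stages)) {
    for (blk in model$stages[[i]]) h <- bottleneck_fwd(h, blk, training)
    if (i <= 2L) taps[[i + 1L]] <- h
  }
  list(logits = linear_fwd(ag_gap2d(h), model$head), taps = taps)
}

#' Forward pass of the convolutional branch
#'
#' Runs a batch of RGB images through a bottleneck residual network and
#' returns the class logits together with the intermediate feature map tapped
#' for the fusion classifier. Tap points are numbered 1-3 from shallow to
#' deep; for 224-px input and the default architecture, tap 3 has per-sample
#' shape (512, 28, 28) (channels, height, width).
#'
#' @param model A branch built by [make_resnet()], or `NULL` to build a
#'   default ResNet-50-shaped branch for `num_classes`.
#' @param batch Numeric array `(N, H, W, 3)` of images in `[0, 1]`, a single
#'   `(H, W, 3)` image, or a list of such images.
#' @param num_classes Number of classes (used only when `model` is `NULL`).
#' @param tap_stage Which tap to return (1, 2 or 3; default 3).
#' @param training Logical; `TRUE` uses batch statistics in the normalization
#'   layers, `FALSE` (default) uses running statistics, making repeated calls
#'   deterministic.
#' @return A `branch_output` list with elements `logits` (`N x M` matrix),
#'   `feature_map` (`(N, h, w, c)` array) and `tap_stage`. Use
#'   [feature_map_shape()] for the per-sample (channels, height, width) shape.
#' @seealso [mvt_forward()], [fusion_forward()]
#' @export
cnn_forward <- function(model = NULL, batch, num_classes = NULL, tap_stage = 3L,
                        training = FALSE) {
  x <- as_image_batch(batch)
  if (dim(x)[4] != 3L) stop("cnn_forward: batch must have 3 channels")
  if (is.null(model)) {
    if (is.null(num_classes)) stop("cnn_forward: give a model or num_classes")
    model <- make_resnet(num_classes)
  }
  tap_stage <- as.integer(tap_stage)
  if (!tap_stage %in% 1:3) stop("cnn_forward: tap_stage must be 1, 2 or 3")
  out <- with_no_grad(resnet_fwd(model, x, training = training))
  branch_output(val(out$logits), val(out$taps[[tap_stage]]), tap_stage)
}

branch_output <- function(logits, feature_map, tap_stage) {
  structure(list(logits = logits, feature_map = feature_map,
                 tap_stage = tap_stage),
            class = "branch_output")
}

#' Per-sample (channels, height, width) shape of a tapped feature map
#'
#' @param x A `branch_output` (from [cnn_forward()] or [mvt_forward()]) or a
#'   feature-map array `(N, h, w, c)`.
#' @return Integer vector `c(channels, height, width)`.
#' @export
feature_map_shape <- function(x) {
  fm <- if (inherits(x, "branch_output")) x$feature_map else x
  d <- dim(fm)
  as.integer(c(d[4], d[2], d[3]))
}

# channel counts of the three CNN taps for a given base width
resnet_tap_channels <- function(base) as.integer(c(base, base * 4L, base * 8L))

# coerce images / lists / labeled_image_set to an (N,H,W,3) array
as_image_batch <- function(batch) {
  if (inherits(batch, "labeled_image_set")) batch <- batch$images
  if (is.list(batch)) {
    n <- length(batch)
    if (n == 0L) stop("empty image batch")
    d <- dim(batch[[1L]])
    out <- array(0, c(n, d))
    for (i in seq_len(n)) out[i, , , ] <- batch[[i]]
    return(out)
  }
  d <- dim(batch)
  if (length(d) == 3L) {
    out <- array(batch, c(1L, d))
    return(out)
  }
  if (length(d) == 4L) return(batch)
  stop("cannot interpret batch of images")
}
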