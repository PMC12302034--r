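# Training configuration: every hyper-parameter in one serializable list.
# Reference defaults follow the published training recipe (Adam, initial
# learning rate 0.01 with first-moment decay 0.8, weight decay 5e-4,
# distillation temperature 4, batch size 64, 300 epochs, 70:30 split,
# 224-px inputs, Mixup x4); `tiny_config()` scales the architecture and
# schedule down for CPU-scale runs on the synthetic data.

#' Build a training configuration
#'
#' @param num_classes Number of classes.
#' @param image_size Input side length in pixels.
#' @param learning_rate Adam step size.
#' @param adam_beta1 First-moment decay (the recipe's "momentum" 0.8; Adam
#'   has no single momentum, and beta1 is its analogue).
#' @param adam_beta2 Second-moment decay.
#' @param weight_decay L2 penalty added to gradients.
#' @param temperature Distillation temperature T for all softened
#'   distributions.
#' @param batch_size,epochs,train_frac,seed Optimization schedule.
#' @param w_epkt,w_fce Weights of the ensemble-to-fusion transfer term and
#'   of the fusion head's supervised cross-entropy; set both to 0 (or
#'   `literal_total = TRUE`) for the bare three-term objective.
#' @param literal_total If `TRUE`, forces `w_epkt = w_fce = 0`.
#' @param mixup A [mixup_config()].
#' @param cnn List: `base` (stem width), `blocks` (per-stage block counts),
#'   `tap_stage` (1-3).
#' @param mvt List: `patch`, `view_dims`, `layers_per_view`, `global_depth`,
#'   `heads`, `mlp_ratio`, `tap_layer`, `multi_view`.
#' @param checkpoint_every Save a checkpoint every this many epochs when an
#'   output directory is given to [train()] (0 = only at the end).
#' @return A `train_config` list.
#' @export
train_config <- function(num_classes = 4L,
                         image_size = 224L,
                         learning_rate = 0.01,
                         adam_beta1 = 0.8,
                         adam_beta2 = 0.999,
                         weight_decay = 5e-4,
                         temperature = 4,
                         batch_size = 64L,
                         epochs = 300L,
                         train_frac = 0.7,
                         seed = 1L,
                         w_epkt = 1,
                         w_fce = 1,
                         literal_total = FALSE,
                         mixup = mixup_config(),
                         cnn = list(base = 64L, blocks = c(3L, 4L, 6L, 3L),
                                    tap_stage = 3L),
                         mvt = list(patch = 16L, view_dims = c(256L, 384L, 512L),
                                    layers_per_view = 4L, global_depth = 4L,
                                    heads = 8L, mlp_ratio = 4L, tap_layer = 3L,
                                    multi_view = TRUE),
                         checkpoint_every = 0L) {
  if (isTRUE(literal_total)) {
    w_epkt <- 0
    w_fce <- 0
  }
  cfg <- list(num_classes = as.integer(num_classes),
              image_size = as.integer(image_size),
              learning_rate = learning_rate, adam_beta1 = adam_beta1,
              adam_beta2 = adam_beta2, weight_decay = weight_decay,
              temperature = temperature, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), train_frac = train_frac,
              seed = as.integer(seed), w_epkt = w_epkt, w_fce = w_fce,
              literal_total = isTRUE(literal_total), mixup = mixup,
              cnn = cnn, mvt = mvt,
              checkpoint_every = as.integer(checkpoint_every))
  stopifnot(cfg$learning_rate > 0, cfg$temperature > 0, cfg$batch_size > 0,
            cfg$epochs >= 0, cfg$train_frac > 0, cfg$train_frac < 1)
  structure(cfg, class = "train_config")
}

#' Reduced configuration for CPU-scale experiments
#'
#' The synthetic-study configuration used throughout the tests and the
#' vignette: 32-px images, stem width 16 with one block per stage, view
#' widths (32, 48, 64) with one layer per view, 2 heads, Mixup x4,
#' 30 epochs, Adam at 2e-3 with mini-batches of 16 (a conventional step
#' size and batch for these reduced widths; the full-scale recipe in
#' `configs/full.yaml` keeps 0.01 and batch 64).
#'
#' @param ... Overrides passed on to [train_config()].
#' @return A `train_config`.
#' @export
tiny_config <- function(...) {
  args <- list(...)
  base <- list(num_classes = 4L, image_size = 32L, learning_rate = 2e-3,
               epochs = 30L, batch_size = 16L,
               mixup = mixup_config(alpha = 0.2, factor = 4L, seed = 1L),
               cnn = list(base = 16L, blocks = c(1L, 1L, 1L, 1L), tap_stage = 3L),
               mvt = list(patch = 8L, view_dims = c(32L, 48L, 64L),
                          layers_per_view = 1L, global_depth = 1L,
                          heads = 2L, mlp_ratio = 2L, tap_layer = 3L,
                          multi_view = TRUE))
  base[names(args)] <- args
  do.call(train_config, base)
}

#' Write a configuration to a YAML file
#' @param cfg A `train_config`. @param path Output file.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "train_config"))
  x <- unclass(cfg)
  x$mixup <- unclass(x$mixup)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a configuration from a YAML file
#' @param path YAML file written by [write_config()] (or hand-edited).
#' @return A `train_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  mix <- x$mixup
  x$mixup <- NULL
  x$cnn$blocks <- as.integer(x$cnn$blocks)
  x$mvt$view_dims <- as.integer(x$mvt$view_dims)
  do.call(train_config, c(x, list(mixup = do.call(mixup_config, mix))))
}
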