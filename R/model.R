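# Dual-branch model assembly, forward pass, prediction and checkpointing.

# flags decide which components exist (ablation variants reuse this)
model_flags <- function(use_cnn = TRUE, use_mvt = TRUE, multi_view = TRUE,
                        use_ec = TRUE, use_afc = TRUE, use_mixup = TRUE) {
  list(use_cnn = use_cnn, use_mvt = use_mvt, multi_view = multi_view,
       use_ec = use_ec, use_afc = use_afc, use_mixup = use_mixup)
}

#' Build a dual-branch mutual-learning model
#'
#' Constructs the convolutional branch, the multi-view transformer branch
#' and (when enabled) the fusion head whose input width is the sum of the
#' two tapped channel counts. Parameter initialization draws from the
#' current RNG state; [train()] seeds it from the configuration.
#'
#' @param cfg A [train_config()].
#' @param flags Component switches (internal; used by
#'   [build_ablation_variant()]).
#' @return An `ofml_model`.
#' @export
build_model <- function(cfg, flags = model_flags()) {
  stopifnot(inherits(cfg, "train_config"))
  M <- cfg$num_classes
  cnn <- NULL
  mvt <- NULL
  fusion <- NULL
  if (flags$use_cnn) {
    cnn <- make_resnet(M, base = cfg$cnn$base, blocks = cfg$cnn$blocks)
  }
  if (flags$use_mvt) {
    mvt <- make_mvt(M, image_size = cfg$image_size, patch = cfg$mvt$patch,
                    view_dims = cfg$mvt$view_dims,
                    layers_per_view = cfg$mvt$layers_per_view,
                    global_depth = cfg$mvt$global_depth, heads = cfg$mvt$heads,
                    mlp_ratio = cfg$mvt$mlp_ratio,
                    multi_view = flags$multi_view && cfg$mvt$multi_view,
                    tap_layer = min(cfg$mvt$tap_layer,
                                    if (flags$multi_view && cfg$mvt$multi_view)
                                      length(cfg$mvt$view_dims) else 1L))
  }
  if (flags$use_afc) {
    if (is.null(cnn) || is.null(mvt)) {
      stop("the fusion classifier needs both branches")
    }
    c1 <- resnet_tap_channels(cfg$cnn$base)[cfg$cnn$tap_stage]
    c2 <- mvt$view_dims[mvt$tap_layer]
    fusion <- make_fusion_head(c1, c2, M)
  }
  norm_env <- new.env(parent = emptyenv())
  norm_env$mean <- c(0.5, 0.5, 0.5)
  norm_env$sd <- c(0.25, 0.25, 0.25)
  structure(list(cnn = cnn, mvt = mvt, fusion = fusion, flags = flags,
                 cfg = cfg, input_norm = norm_env), class = "ofml_model")
}

# per-channel input standardization (set from the training data by train())
set_input_norm <- function(model, data) {
  x <- as_image_batch(data)
  model$input_norm$mean <- apply(x, 4L, mean)
  model$input_norm$sd <- pmax(apply(x, 4L, stats::sd), 1e-3)
  invisible(model)
}

normalize_input <- function(model, x) {
  mu <- model$input_norm$mean
  sd <- model$input_norm$sd
  for (ch in seq_len(dim(x)[4])) {
    x[, , , ch] <- (x[, , , ch] - mu[ch]) / sd[ch]
  }
  x
}

#' @export
print.ofml_model <- function(x, ...) {
  on <- function(b) if (b) "on" else "off"
  cat(sprintf(paste0("<ofml_model> %d classes, %d px | cnn: %s, transformer: %s",
                     " (multi-view %s), ensemble: %s, fusion: %s\n"),
              x$cfg$num_classes, x$cfg$image_size, on(x$flags$use_cnn),
              on(x$flags$use_mvt), on(x$flags$multi_view), on(x$flags$use_ec),
              on(x$flags$use_afc)))
  cat(sprintf("  parameters: %d\n", n_parameters(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model An `ofml_model` or fitted object.
#' @return Integer count of scalar parameters.
#' @export
n_parameters <- function(model) {
  if (inherits(model, "ofml_fit")) model <- model$model
  sum(vapply(collect_params(unclass(model)[c("cnn", "mvt", "fusion")]),
             function(p) length(p$value), numeric(1)))
}

# Forward pass of every active component. Returns nodes: z1, z2, zf, fm1, fm2.
model_forward <- function(model, x, training = FALSE) {
  flags <- model$flags
  cfg <- model$cfg
  x <- normalize_input(model, x)
  z1 <- z2 <- zf <- fm1 <- fm2 <- NULL
  if (flags$use_cnn) {
    out1 <- resnet_fwd(model$cnn, x, training = training)
    z1 <- out1$logits
    if (flags$use_afc) fm1 <- out1$taps[[cfg$cnn$tap_stage]]
  }
  if (flags$use_mvt) {
    out2 <- mvt_fwd(model$mvt, x)
    z2 <- out2$logits
    if (flags$use_afc) fm2 <- out2$taps[[as.character(model$mvt$tap_layer)]]
  }
  if (flags$use_afc) zf <- fusion_fwd(model$fusion, fm1, fm2)
  list(z1 = z1, z2 = z2, zf = zf, fm1 = fm1, fm2 = fm2)
}

#' Predict class probabilities and labels
#'
#' Classification comes from the fusion classifier's softmax (temperature 1)
#' when the model has one; branch-level and ensemble probabilities are also
#' returned for ablation and inspection. Models without a fusion head fall
#' back to the ensemble (or the single branch).
#'
#' @param object An `ofml_model` or `ofml_fit`.
#' @param newdata Images: `labeled_image_set`, `(N,H,W,3)` array, single
#'   image or list of images.
#' @param ... Unused.
#' @return List with `probs` (N x M), `labels` (0-based argmax), and the
#'   per-head probability matrices `branch1`, `branch2`, `ensemble`,
#'   `fusion` (those that exist).
#' @export
predict.ofml_model <- function(object, newdata, ...) {
  x <- as_image_batch(newdata)
  if (dim(x)[2] != object$cfg$image_size) {
    stop("image size does not match the training configuration (",
         object$cfg$image_size, " px)")
  }
  out <- with_no_grad(model_forward(object, x, training = FALSE))
  heads <- list()
  if (!is.null(out$z1)) heads$branch1 <- softmax_rows(val(out$z1))
  if (!is.null(out$z2)) heads$branch2 <- softmax_rows(val(out$z2))
  if (!is.null(out$z1) && !is.null(out$z2)) {
    heads$ensemble <- softmax_rows(ensemble_logits(val(out$z1), val(out$z2)))
  }
  if (!is.null(out$zf)) heads$fusion <- softmax_rows(val(out$zf))
  probs <- if (!is.null(heads$fusion)) heads$fusion
           else if (!is.null(heads$ensemble)) heads$ensemble
           else if (!is.null(heads$branch1)) heads$branch1
           else heads$branch2
  c(list(probs = probs, labels = max.col(probs) - 1L), heads)
}

#' @export
predict.ofml_fit <- function(object, newdata, ...) {
  predict.ofml_model(object$model, newdata, ...)
}

# ---- checkpointing ----------------------------------------------------------

# Parameters and normalization running statistics, in deterministic
# traversal order, as plain numeric arrays.
model_state <- function(model) {
  comp <- unclass(model)[c("cnn", "mvt", "fusion")]
  list(values = lapply(collect_params(comp), function(p) p$value),
       bn = lapply(collect_bn_states(comp), function(s) {
         list(mean = s$mean, var = s$var)
       }),
       input_norm = list(mean = model$input_norm$mean,
                         sd = model$input_norm$sd))
}

collect_bn_states <- function(x) {
  out <- list()
  rec <- function(v) {
    if (is.environment(v) && !is.null(v$mean) && !inherits(v, "ag_node")) {
      out[[length(out) + 1L]] <<- v
    } else if (is.list(v)) {
      for (e in v) rec(e)
    }
  }
  rec(x)
  out
}

restore_model_state <- function(model, state) {
  comp <- unclass(model)[c("cnn", "mvt", "fusion")]
  ps <- collect_params(comp)
  stopifnot(length(ps) == length(state$values))
  for (i in seq_along(ps)) ps[[i]]$value <- state$values[[i]]
  bs <- collect_bn_states(comp)
  stopifnot(length(bs) == length(state$bn))
  for (i in seq_along(bs)) {
    bs[[i]]$mean <- state$bn[[i]]$mean
    bs[[i]]$var <- state$bn[[i]]$var
  }
  if (!is.null(state$input_norm)) {
    model$input_norm$mean <- state$input_norm$mean
    model$input_norm$sd <- state$input_norm$sd
  }
  invisible(model)
}

#' Save a model (or fit) checkpoint
#'
#' Stores the configuration, component flags, all parameter values and the
#' normalization running statistics.
#'
#' @param object `ofml_model` or `ofml_fit`. @param path Output `.rds` file.
#' @export
save_checkpoint <- function(object, path) {
  model <- if (inherits(object, "ofml_fit")) object$model else object
  history <- if (inherits(object, "ofml_fit")) object$history else NULL
  saveRDS(list(cfg = model$cfg, flags = model$flags,
               state = model_state(model), history = history), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the architecture from the stored configuration and restores all
#' parameters, yielding predictions identical to the saved model's.
#'
#' @param path File written by [save_checkpoint()].
#' @return An `ofml_fit` (with the stored history, possibly `NULL`).
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg, ck$flags)
  restore_model_state(model, ck$state)
  structure(list(model = model, history = ck$history, config = ck$cfg),
            class = "ofml_fit")
}
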