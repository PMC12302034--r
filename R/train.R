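# Joint optimization of both backbones and the fusion head: one backward
# pass on the summed objective per mini-batch, so every component is updated
# simultaneously.

#' Train a dual-branch model by online fusion mutual learning
#'
#' Applies Mixup expansion to the training images (per the configuration),
#' then iterates mini-batches: forward both branches, form the ensemble and
#' fusion logits, assemble every loss term, and take one Adam step on the
#' total. All randomness (initialization, Mixup, shuffling) derives from
#' `cfg$seed`, so two runs with the same configuration and data are
#' identical.
#'
#' @param cfg A [train_config()] (or [tiny_config()]).
#' @param data Training `labeled_image_set` (at least 2 classes).
#' @param eval_data Optional held-out set; its accuracy is recorded per epoch.
#' @param model Optional pre-built `ofml_model` (used by the ablation
#'   harness); default builds one from `cfg`.
#' @param out_dir Optional directory for checkpoints and the history CSV.
#' @param verbose Print one line per epoch.
#' @return An `ofml_fit`: list with `model`, `history` (one tibble row per
#'   epoch: every loss component plus train/eval accuracy), `config`.
#' @export
train <- function(cfg, data, eval_data = NULL, model = NULL, out_dir = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), inherits(data, "labeled_image_set"))
  if (length(unique(data$labels)) < 2L) {
    stop("training data must contain at least 2 classes")
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  if (is.null(model)) model <- build_model(cfg)
  set_input_norm(model, data)
  flags <- model$flags
  train_set <- data
  if (flags$use_mixup && cfg$mixup$factor > 1L) {
    train_set <- expand_dataset(data, cfg$mixup)
  }
  n <- length(train_set$images)
  xall <- as_image_batch(train_set$images)
  yall <- label_matrix(train_set)
  params <- collect_params(unclass(model)[c("cnn", "mvt", "fusion")])
  history <- list()
  step <- 0L
  T <- cfg$temperature
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    sums <- NULL
    nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- xall[idx, , , , drop = FALSE]
      yb <- yall[idx, , drop = FALSE]
      fwd <- model_forward(model, xb, training = TRUE)
      lb <- loss_bundle_nodes(fwd$z1, fwd$z2,
                              if (flags$use_afc) fwd$zf else NULL,
                              yb, T,
                              w_epkt = if (flags$use_ec && flags$use_afc) cfg$w_epkt else 0,
                              w_fce = cfg$w_fce)
      if (!flags$use_ec) {
        lb$parts$L_ensemble <- NULL
        lb$parts$L_EPKT <- NULL
        # rebuild total without the ensemble terms
        tot <- NULL
        addt <- function(a, b) if (is.null(a)) b else ag_add(a, b)
        if (!is.null(lb$parts$L1)) tot <- addt(tot, lb$parts$L1)
        if (!is.null(lb$parts$L2)) tot <- addt(tot, lb$parts$L2)
        if (!is.null(lb$parts$L_fusion_ce) && cfg$w_fce != 0) {
          tot <- addt(tot, ag_scale(lb$parts$L_fusion_ce, cfg$w_fce))
        }
        lb$total <- tot
        lb$parts$L_f <- tot
      }
      vals <- vapply(lb$parts, function(p) val(p), numeric(1))
      if (any(!is.finite(vals))) {
        bad <- names(vals)[which(!is.finite(vals))[1L]]
        stop("training diverged: first non-finite loss component is ", bad)
      }
      ag_backward(lb$total)
      step <- step + 1L
      adam_step(params, lr = cfg$learning_rate, beta1 = cfg$adam_beta1,
                beta2 = cfg$adam_beta2, weight_decay = cfg$weight_decay,
                t = step)
      zero_grads(params)
      sums <- if (is.null(sums)) vals else sums + vals
      nb <- nb + 1L
    }
    row <- as.list(sums / nb)
    row$epoch <- epoch
    row$train_accuracy <- accuracy_on(model, data)
    if (!is.null(eval_data)) row$eval_accuracy <- accuracy_on(model, eval_data)
    history[[epoch]] <- tibble::as_tibble(row[c("epoch",
                                                setdiff(names(row), "epoch"))])
    if (verbose) {
      message(sprintf("epoch %3d | L_f %.4f | train acc %.3f", epoch,
                      row$L_f, row$train_accuracy))
    }
    if (!is.null(out_dir) && cfg$checkpoint_every > 0L &&
        epoch %% cfg$checkpoint_every == 0L) {
      save_checkpoint(model, file.path(out_dir, sprintf("epoch_%04d.rds", epoch)))
    }
  }
  hist <- if (length(history) > 0L) do.call(rbind, history) else
    tibble::tibble(epoch = integer(0))
  fit <- structure(list(model = model, history = hist, config = cfg),
                   class = "ofml_fit")
  if (!is.null(out_dir)) {
    save_checkpoint(fit, file.path(out_dir, "checkpoint.rds"))
    utils::write.csv(hist, file.path(out_dir, "history.csv"), row.names = FALSE)
  }
  fit
}

accuracy_on <- function(model, data) {
  pr <- predict.ofml_model(model, data)
  mean(pr$labels == data$labels)
}

#' @export
print.ofml_fit <- function(x, ...) {
  cat(sprintf("<ofml_fit> %d epochs", nrow(x$history)))
  if (nrow(x$history) > 0L) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf(" | final L_f %.4f | train acc %.3f",
                last$L_f, last$train_accuracy))
  }
  cat("\n")
  print(x$model)
  invisible(x)
}

#' Turn a fitted object into a tidy tibble
#' @param x Object. @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Tidy per-epoch training history
#'
#' @param x An `ofml_fit`.
#' @param ... Unused.
#' @return Tibble in long format: `epoch`, `component`, `value`.
#' @export
tidy.ofml_fit <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0L) {
    return(tibble::tibble(epoch = integer(0), component = character(0),
                          value = numeric(0)))
  }
  comps <- setdiff(names(h), "epoch")
  out <- lapply(comps, function(cn) {
    tibble::tibble(epoch = h$epoch, component = cn, value = h[[cn]])
  })
  do.call(rbind, out)
}
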