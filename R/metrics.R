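# Evaluation metrics: accuracy, macro precision/recall/F1, one-vs-rest
# macro AUC (midrank Mann-Whitney statistic), and the confusion matrix.

#' Classification metrics
#'
#' Computes accuracy, macro-averaged precision, recall and F1, the M x M
#' confusion matrix, and (when scores are given) the one-vs-rest AUC
#' averaged over classes. AUC uses the midrank form of the Mann-Whitney
#' statistic, so tied scores contribute 1/2 and identical scores for all
#' samples give 0.5. Classes absent from `y_true` have no defined
#' one-vs-rest AUC and are excluded from the macro average with a warning.
#'
#' @param y_true,y_pred 0-based class labels of equal length.
#' @param y_score Optional N x M row-stochastic probability matrix.
#' @param n_classes Number of classes M (default: inferred).
#' @return A `metric_report` list: `accuracy`, `precision`, `recall`, `f1`,
#'   `auc`, `confusion_matrix` (rows = truth, columns = prediction) and a
#'   `per_class` tibble.
#' @export
compute_metrics <- function(y_true, y_pred, y_score = NULL, n_classes = NULL) {
  if (length(y_true) != length(y_pred)) stop("label length mismatch")
  if (is.null(n_classes)) {
    n_classes <- max(c(y_true, y_pred,
                       if (!is.null(y_score)) ncol(y_score) - 1L)) + 1L
  }
  M <- as.integer(n_classes)
  if (!is.null(y_score)) {
    stopifnot(nrow(y_score) == length(y_true), ncol(y_score) == M)
    if (any(abs(rowSums(y_score) - 1) > 1e-6)) {
      stop("y_score rows must sum to 1")
    }
  }
  cm <- matrix(0L, M, M, dimnames = list(true = 0:(M - 1), pred = 0:(M - 1)))
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  tp <- unname(diag(cm))
  prec <- unname(ifelse(colSums(cm) > 0, tp / colSums(cm), 0))
  rec <- unname(ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0))
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  auc_k <- rep(NA_real_, M)
  if (!is.null(y_score)) {
    for (k in seq_len(M)) {
      pos <- y_true == (k - 1L)
      if (!any(pos) || all(pos)) next
      auc_k[k] <- auc_rank(y_score[, k], pos)
    }
    if (any(is.na(auc_k))) {
      warning("classes absent from y_true excluded from the macro AUC: ",
              paste(which(is.na(auc_k)) - 1L, collapse = ", "))
    }
  }
  structure(list(
    accuracy = mean(y_true == y_pred),
    precision = mean(prec),
    recall = mean(rec),
    f1 = mean(f1),
    auc = if (is.null(y_score)) NA_real_ else mean(auc_k, na.rm = TRUE),
    confusion_matrix = cm,
    per_class = tibble::tibble(class = 0:(M - 1), precision = prec,
                               recall = rec, f1 = f1, auc = auc_k,
                               support = unname(rowSums(cm)))),
    class = "metric_report")
}

# one-vs-rest AUC by midranks: P(score_pos > score_neg) + 0.5 P(equal)
auc_rank <- function(score, positive) {
  r <- rank(score)  # midranks
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("<metric_report> accuracy %.4f | precision %.4f | ",
                     "recall %.4f | F1 %.4f | AUC %s\n"),
              x$accuracy, x$precision, x$recall, x$f1,
              if (is.na(x$auc)) "-" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' One-row summary of a metric report
#' @param x A `metric_report`. @param ... Unused.
#' @return One-row tibble with the five headline metrics.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname glance
#' @export
glance.metric_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall, f1 = x$f1, auc = x$auc,
                 n = sum(x$confusion_matrix))
}

#' Evaluate a fitted model on an image set
#'
#' Convenience wrapper: predicts with the fusion head and computes
#' [compute_metrics()] against the set's labels.
#'
#' @param fit An `ofml_fit` or `ofml_model`. @param data A
#'   `labeled_image_set`.
#' @return A `metric_report`.
#' @export
evaluate <- function(fit, data) {
  pr <- if (inherits(fit, "ofml_fit")) predict(fit, data) else
    predict.ofml_model(fit, data)
  compute_metrics(data$labels, pr$labels, pr$probs,
                  n_classes = length(data$class_names))
}

# one-vs-rest ROC points for each class (used by the CLI's roc.csv)
roc_points <- function(y_true, y_score) {
  M <- ncol(y_score)
  out <- list()
  for (k in seq_len(M)) {
    pos <- y_true == (k - 1L)
    if (!any(pos) || all(pos)) next
    th <- sort(unique(y_score[, k]), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(y_score[pos, k] >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(y_score[!pos, k] >= t), numeric(1))
    out[[length(out) + 1L]] <- tibble::tibble(
      class = k - 1L, threshold = th, fpr = fpr, tpr = tpr)
  }
  do.call(rbind, out)
}
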