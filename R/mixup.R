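# Mixup training-set expansion: convex combinations of image pairs and of
# their label distributions, with Beta(alpha, alpha) mixing weights.

#' Mixup configuration
#'
#' @param alpha Beta-distribution concentration (> 0); mixing weights are
#'   drawn as `lam ~ Beta(alpha, alpha)`.
#' @param factor Integer expansion multiple (>= 1); the output has exactly
#'   `factor` times as many images as the input.
#' @param seed RNG seed for the mixing weights and partner draws.
#' @param include_originals If `TRUE` (default) the first copy of the output
#'   is the untouched originals and the remaining `factor - 1` copies are
#'   mixed samples.
#' @param within_class If `TRUE`, mixing partners are drawn from the same
#'   class; default `FALSE` draws partners uniformly from the whole set.
#' @return A `mixup_config` list.
#' @export
mixup_config <- function(alpha = 0.2, factor = 4L, seed = 1L,
                         include_originals = TRUE, within_class = FALSE) {
  if (!is.numeric(alpha) || alpha <= 0) stop("mixup alpha must be positive")
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("mixup factor must be at least 1")
  structure(list(alpha = alpha, factor = factor, seed = as.integer(seed),
                 include_originals = isTRUE(include_originals),
                 within_class = isTRUE(within_class)),
            class = "mixup_config")
}

#' Mix one pair of images and label distributions
#'
#' `x = lam * x_i + (1 - lam) * x_j` pixel-wise and
#' `y = lam * y_i + (1 - lam) * y_j`; the mixed label stays on the simplex.
#'
#' @param x_i,x_j Images of identical shape.
#' @param y_i,y_j Label distributions on the M-simplex (one-hot allowed).
#' @param lam Mixing weight in `[0, 1]`.
#' @return List with `image` and `label`.
#' @export
mixup_pair <- function(x_i, y_i, x_j, y_j, lam) {
  if (!identical(dim(x_i), dim(x_j))) stop("mixup_pair: image shape mismatch")
  if (length(y_i) != length(y_j)) stop("mixup_pair: label length mismatch")
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0 || lam > 1) {
    stop("mixup_pair: lam must lie in [0, 1]")
  }
  chk <- function(y) {
    if (any(y < -1e-8) || abs(sum(y) - 1) > 1e-6) {
      stop("mixup_pair: labels must lie on the probability simplex")
    }
  }
  chk(y_i); chk(y_j)
  list(image = lam * x_i + (1 - lam) * x_j,
       label = lam * y_i + (1 - lam) * y_j)
}

#' Expand a training set by Mixup
#'
#' Returns exactly `factor` times the input size: the originals (when
#' `include_originals`) followed by `factor - 1` rounds of mixed samples,
#' each original paired with a partner drawn under the configured seed.
#' Output labels are soft (`label_probs` rows on the simplex); the `labels`
#' field holds the argmax class for convenience.
#'
#' @param data A non-empty `labeled_image_set`.
#' @param cfg A [mixup_config()].
#' @return A `labeled_image_set` with `factor * length(data)` images.
#' @export
expand_dataset <- function(data, cfg) {
  stopifnot(inherits(data, "labeled_image_set"), inherits(cfg, "mixup_config"))
  n <- length(data$images)
  if (n == 0L) stop("expand_dataset: input set is empty")
  if (cfg$factor == 1L && cfg$include_originals) return(data)
  Y <- label_matrix(data)
  images <- vector("list", cfg$factor * n)
  probs <- matrix(0, cfg$factor * n, ncol(Y))
  pos <- 0L
  n_mix_rounds <- cfg$factor - as.integer(cfg$include_originals)
  if (cfg$include_originals) {
    for (i in seq_len(n)) images[[i]] <- data$images[[i]]
    probs[seq_len(n), ] <- Y
    pos <- n
  }
  with_seed(cfg$seed, {
    for (r in seq_len(n_mix_rounds)) {
      lam <- stats::rbeta(n, cfg$alpha, cfg$alpha)
      partner <- if (cfg$within_class) {
        vapply(seq_len(n), function(i) {
          ik <- which(data$labels == data$labels[i])
          ik[sample.int(length(ik), 1L)]
        }, integer(1))
      } else {
        sample.int(n, n, replace = TRUE)
      }
      for (i in seq_len(n)) {
        m <- mixup_pair(data$images[[i]], Y[i, ],
                        data$images[[partner[i]]], Y[partner[i], ], lam[i])
        pos <- pos + 1L
        images[[pos]] <- m$image
        probs[pos, ] <- m$label
      }
    }
  })
  labeled_image_set(images, max.col(probs) - 1L, data$class_names,
                    source = data$source, label_probs = probs)
}
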