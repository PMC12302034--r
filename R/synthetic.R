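# Synthetic histology-like images: dark elliptical "nuclei" scattered on a
# pink eosin-like background. Classes differ in blob count, radius range and
# stain darkness, which makes them separable even by a pixel-mean centroid
# rule — so classifier tests have a known-easy target.

#' Specification for a synthetic image set
#'
#' @param n_classes Number of classes (>= 2).
#' @param per_class Images per class (>= 0).
#' @param image_size Side length in pixels (>= 32).
#' @param seed RNG seed; the same spec and seed give bit-identical images.
#' @param texture_params Optional list with one entry per class, each a list
#'   `density` (expected blob count at 64 px, scaled by area), `radius`
#'   (fraction-of-side range, length 2), `darkness` (0-1 blob opacity) and
#'   `hue` (RGB blob colour). Defaults spread the classes apart.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_classes = 4L, per_class = 25L, image_size = 64L,
                           seed = 1L, texture_params = NULL) {
  n_classes <- as.integer(n_classes)
  per_class <- as.integer(per_class)
  image_size <- as.integer(image_size)
  if (is.na(n_classes) || n_classes < 2L) {
    stop("synthetic_spec: n_classes must be at least 2")
  }
  if (per_class < 0L) stop("synthetic_spec: per_class must be non-negative")
  if (is.na(image_size) || image_size < 32L) {
    stop("synthetic_spec: image_size must be at least 32")
  }
  if (is.null(texture_params)) {
    texture_params <- lapply(seq_len(n_classes), function(k) {
      list(density = 6 + 12 * (k - 1L),
           radius = c(0.05, 0.09) + 0.01 * ((k - 1L) %% 3L),
           darkness = 0.5 + 0.35 * (k - 1L) / max(1L, n_classes - 1L),
           hue = c(0.30, 0.18, 0.46) + 0.04 * ((k - 1L) %% 2L))
    })
  }
  if (length(texture_params) != n_classes) {
    stop("texture_params must have one entry per class")
  }
  structure(list(n_classes = n_classes, per_class = per_class,
                 image_size = image_size, seed = as.integer(seed),
                 texture_params = texture_params),
            class = "synthetic_spec")
}

# run expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

draw_synthetic_image <- function(size, tp) {
  px <- seq_len(size)
  gx <- matrix(px, size, size)
  gy <- matrix(px, size, size, byrow = TRUE)
  # eosin-pink background with gentle large-scale variation
  base <- c(0.91, 0.75, 0.82)
  wave <- 0.02 * sin(2 * pi * gx / size + stats::runif(1, 0, 2 * pi)) *
    cos(2 * pi * gy / size + stats::runif(1, 0, 2 * pi))
  img <- array(0, c(size, size, 3L))
  for (ch in 1:3) img[, , ch] <- base[ch] + wave
  n_blobs <- stats::rpois(1L, tp$density * (size / 64)^2)
  mask_any <- matrix(FALSE, size, size)
  for (b in seq_len(n_blobs)) {
    cx <- stats::runif(1, 1, size)
    cy <- stats::runif(1, 1, size)
    rx <- stats::runif(1, tp$radius[1], tp$radius[2]) * size
    ry <- stats::runif(1, tp$radius[1], tp$radius[2]) * size
    th <- stats::runif(1, 0, pi)
    dx <- (gx - cx) * cos(th) + (gy - cy) * sin(th)
    dy <- -(gx - cx) * sin(th) + (gy - cy) * cos(th)
    r2 <- (dx / rx)^2 + (dy / ry)^2
    a <- pmax(0, 1 - r2)           # soft-edged ellipse
    a <- sqrt(a) * tp$darkness
    inside <- r2 <= 1
    mask_any <- mask_any | inside
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] * (1 - a) + tp$hue[ch] * a
    }
  }
  img <- img + array(stats::rnorm(size * size * 3L, 0, 0.015), dim(img))
  img <- pmin(pmax(img, 0), 1)
  attr(img, "blob_mask") <- mask_any
  img
}

#' Generate a class-separable synthetic image set
#'
#' Draws `per_class` images per class with the class's texture parameters.
#' Deterministic for a fixed spec (seed included): calling twice yields
#' byte-identical images.
#'
#' @param spec A [synthetic_spec()].
#' @param keep_masks Logical; if `TRUE`, each image carries a logical
#'   `blob_mask` attribute marking nucleus pixels (used by the Grad-CAM
#'   sanity checks).
#' @return A `labeled_image_set`: list with `images` (list of `(H, W, 3)`
#'   arrays in `[0, 1]`), `labels` (0-based integer classes), `class_names`,
#'   and `source = "synthetic"`.
#' @export
generate_synthetic_dataset <- function(spec, keep_masks = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  M <- spec$n_classes
  class_names <- sprintf("class%02d", seq_len(M))
  images <- list()
  labels <- integer(0)
  if (spec$per_class > 0L) {
    images <- vector("list", M * spec$per_class)
    labels <- integer(M * spec$per_class)
    with_seed(spec$seed, {
      i <- 0L
      for (k in seq_len(M)) {
        tp <- spec$texture_params[[k]]
        for (j in seq_len(spec$per_class)) {
          i <- i + 1L
          img <- draw_synthetic_image(spec$image_size, tp)
          if (!keep_masks) attr(img, "blob_mask") <- NULL
          images[[i]] <- img
          labels[i] <- k - 1L
        }
      }
    })
  }
  labeled_image_set(images, labels, class_names, source = "synthetic")
}

#' Construct a labeled image set
#'
#' The shared container for generated and folder-loaded data: a list of
#' equal-size `(H, W, 3)` arrays with 0-based integer labels.
#'
#' @param images List of `(H, W, 3)` numeric arrays in `[0, 1]`.
#' @param labels Integer class indices in `[0, M)`.
#' @param class_names Character vector of the M class names.
#' @param source `"synthetic"` or `"folder"`.
#' @param metadata Optional tibble of per-image metadata (e.g. file path and
#'   magnification).
#' @param label_probs Optional `N x M` soft-label matrix (rows on the
#'   simplex), set by [expand_dataset()].
#' @return A `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, class_names,
                              source = c("synthetic", "folder"),
                              metadata = NULL, label_probs = NULL) {
  source <- match.arg(source)
  labels <- as.integer(labels)
  if (length(images) != length(labels)) {
    stop("images and labels must have equal length")
  }
  M <- length(class_names)
  if (length(labels) > 0L && any(labels < 0L | labels >= M)) {
    stop("labels must lie in [0, number of classes)")
  }
  if (length(images) > 1L) {
    d1 <- dim(images[[1L]])
    same <- vapply(images, function(im) identical(dim(im), d1), logical(1))
    if (!all(same)) stop("all images must share the same dimensions")
  }
  structure(list(images = images, labels = labels, class_names = class_names,
                 source = source, metadata = metadata,
                 label_probs = label_probs),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  d <- if (length(x$images) > 0L) paste(dim(x$images[[1L]]), collapse = "x")
       else "none"
  cat(sprintf("<labeled_image_set> %d images (%s), %d classes, source: %s\n",
              length(x$images), d, length(x$class_names), x$source))
  if (length(x$labels) > 0L) {
    tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                        labels = x$class_names))
    print(tab)
  }
  invisible(x)
}

#' @export
length.labeled_image_set <- function(x) length(x$images)

# subset by index vector, preserving metadata and soft labels
subset_image_set <- function(data, idx) {
  labeled_image_set(
    data$images[idx], data$labels[idx], data$class_names, data$source,
    metadata = if (!is.null(data$metadata)) data$metadata[idx, , drop = FALSE],
    label_probs = if (!is.null(data$label_probs)) {
      data$label_probs[idx, , drop = FALSE]
    })
}

# one-hot (or stored soft) label matrix of a set
label_matrix <- function(data) {
  M <- length(data$class_names)
  if (!is.null(data$label_probs)) return(data$label_probs)
  oh <- matrix(0, length(data$labels), M)
  if (length(data$labels) > 0L) {
    oh[cbind(seq_along(data$labels), data$labels + 1L)] <- 1
  }
  oh
}
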