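# Shared fixtures. Expensive objects (the tiny trained study, the 224-px
# forward passes) are built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# the frozen tiny-study dataset: 4 classes x 25 images at 32 px
tiny_study_data <- function() {
  if (is.null(.fixtures$data)) {
    .fixtures$data <- generate_synthetic_dataset(
      synthetic_spec(n_classes = 4, per_class = 25, image_size = 32, seed = 7))
  }
  .fixtures$data
}

# the tiny mutual-learning fit (full model, Mixup x4, 30 epochs)
tiny_study_fit <- function() {
  if (is.null(.fixtures$fit)) {
    .fixtures$fit <- train(tiny_config(seed = 7), tiny_study_data())
  }
  .fixtures$fit
}

# full-scale branch forwards at 224 px (shape contracts)
shapes_224 <- function() {
  if (is.null(.fixtures$s224)) {
    set.seed(1)
    x <- array(stats::runif(224 * 224 * 3), c(1, 224, 224, 3))
    .fixtures$s224 <- list(
      cnn = cnn_forward(NULL, x, num_classes = 8, tap_stage = 3),
      mvt = mvt_forward(NULL, x, num_classes = 8))
  }
  .fixtures$s224
}

# fast micro configuration for structural / smoke tests
micro_config <- function(...) {
  tiny_config(epochs = 2L, batch_size = 8L,
              cnn = list(base = 8L, blocks = c(1L, 1L, 1L, 1L), tap_stage = 3L),
              mvt = list(patch = 8L, view_dims = c(8L, 12L, 16L),
                         layers_per_view = 1L, global_depth = 1L,
                         heads = 2L, mlp_ratio = 2L, tap_layer = 3L,
                         multi_view = TRUE),
              ...)
}

micro_data <- function(per_class = 4, seed = 11) {
  generate_synthetic_dataset(
    synthetic_spec(n_classes = 4, per_class = per_class, image_size = 32,
                   seed = seed))
}

# independent oracle: nearest-centroid classifier on raw pixels
centroid_accuracy <- function(d) {
  X <- t(vapply(d$images, as.vector, numeric(length(d$images[[1]]))))
  ks <- sort(unique(d$labels))
  cents <- vapply(ks, function(k) colMeans(X[d$labels == k, , drop = FALSE]),
                  numeric(ncol(X)))
  pred <- apply(X, 1, function(r) ks[which.min(colSums((cents - r)^2))])
  mean(pred == d$labels)
}

# numeric softmax used by hand-arithmetic oracles in the loss tests
oracle_softmax <- function(z) exp(z) / sum(exp(z))

expect_on_simplex <- function(p, tol = 1e-8) {
  expect_true(all(p >= -tol))
  if (is.matrix(p)) {
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)
  } else {
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
}
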