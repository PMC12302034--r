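# Metrics, Grad-CAM reductions and the 2-D feature embedding.

test_that("metrics match a hand-counted contingency table", {
  r <- compute_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(r$accuracy, 0.75)
  expect_equal(r$per_class$precision, c(1, 2 / 3))
  expect_equal(r$per_class$recall, c(0.5, 1))
  expect_identical(as.vector(r$confusion_matrix), c(1L, 0L, 1L, 2L))
  # accuracy from the confusion matrix equals direct accuracy
  expect_equal(sum(diag(r$confusion_matrix)) / sum(r$confusion_matrix),
               r$accuracy)

  perfect <- compute_metrics(0:3, 0:3, diag(4))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  expect_true(all(diag(perfect$confusion_matrix) == 1))
  g <- glance(perfect)
  expect_identical(g$n, 4L)
})

test_that("rank-based AUC handles ties, monotone transforms, and absent classes", {
  # identical scores for every sample: pure ties, AUC 1/2
  sc <- matrix(0.5, 4, 2)
  r <- compute_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1), sc)
  expect_equal(r$auc, 0.5)
  # invariance under strictly monotone transforms of the scores
  set.seed(14)
  y <- rep(0:1, each = 10)
  s <- cbind(runif(20), 0)
  s[, 2] <- 1 - s[, 1]
  a1 <- compute_metrics(y, y, s)$auc
  s2 <- cbind(plogis(5 * s[, 1] - 2), 0)
  s2[, 2] <- 1 - s2[, 1]
  expect_equal(compute_metrics(y, y, s2)$auc, a1)
  # absent class excluded with a warning
  sc3 <- matrix(1 / 3, 6, 3)
  sc3[, 1] <- c(0.9, 0.8, 0.2, 0.1, 0.3, 0.2)
  sc3 <- sc3 / rowSums(sc3)
  expect_warning(r3 <- compute_metrics(c(0, 0, 1, 1, 1, 0), rep(0, 6), sc3,
                                       n_classes = 3), "absent")
  expect_true(is.na(r3$per_class$auc[3]))
  expect_false(is.na(r3$auc))
})

test_that("rank AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  y <- rbinom(40, 1, 0.5)
  s <- runif(40)
  ours <- asNamespace("ofml")$auc_rank(s, y == 1)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the Grad-CAM reduction is normalized, sized, and closed-form under uniform gradients", {
  set.seed(16)
  act <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  grad <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  cam <- cam_from_activation(act, grad, out_size = c(32, 32))
  expect_identical(dim(cam), c(32L, 32L))
  expect_gte(min(cam), 0)
  expect_lte(max(cam), 1)
  # uniform positive gradients: channel weights are all 1, so the heatmap is
  # the rectified channel-sum map, min-max normalized
  gu <- array(1, c(4, 4, 3))
  cam_u <- cam_from_activation(act, gu)
  ref <- pmax(act[, , 1] + act[, , 2] + act[, , 3], 0)
  ref <- (ref - min(ref)) / (max(ref) - min(ref))
  expect_equal(cam_u, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Grad-CAM maxima land in the nucleus-blob region on held-out images", {
  # Localization is only a meaningful expectation where the class evidence IS
  # the nuclei: the sparsest synthetic class is recognized by their absence,
  # so its heatmap rightly peaks on clean background. The check therefore
  # covers held-out images with appreciable nucleus coverage (>= 5%).
  fit <- tiny_study_fit()
  held <- generate_synthetic_dataset(
    synthetic_spec(n_classes = 4, per_class = 5, image_size = 32, seed = 99),
    keep_masks = TRUE)
  hits <- 0L
  n <- 0L
  for (i in seq_along(held$images)) {
    img <- held$images[[i]]
    cam <- grad_cam(fit, img, tap = "fusion-input")
    expect_identical(dim(cam), c(32L, 32L))
    expect_gte(min(cam), 0)
    expect_lte(max(cam), 1)
    mask <- attr(img, "blob_mask")
    if (mean(mask) < 0.05) next
    n <- n + 1L
    # dilate the blob mask by the tap's upsampling half-stride (4 px): a CAM
    # cell covers an 8x8 pixel block at this tap
    dm <- EBImage::dilate(EBImage::Image(mask * 1),
                          EBImage::makeBrush(9, "disc")) > 0
    peak <- which(cam == max(cam), arr.ind = TRUE)[1, ]
    if (dm[peak[1], peak[2]]) hits <- hits + 1L
  }
  expect_gte(n, 10L)
  expect_gte(hits / n, 0.8)
  expect_error(grad_cam(fit, held$images[[1]], target_class = 9), "range")
})

test_that("fused model features embed into class-consistent 2-D clusters", {
  fit <- tiny_study_fit()
  d <- tiny_study_data()
  feats <- model_features(fit, d)
  expect_identical(dim(feats), c(100L, 128L + 64L))  # cnn tap + view-3 channels
  emb <- embed_features_2d(feats, d$labels, seed = 2)
  expect_identical(nrow(emb), 100L)
  expect_identical(emb$label, d$labels)
})

test_that("the 2-D embedding recovers separated clusters and is deterministic", {
  set.seed(17)
  f <- rbind(matrix(rnorm(30 * 5, 0), 30, 5), matrix(rnorm(30 * 5, 8), 30, 5))
  lab <- rep(0:1, each = 30)
  emb <- embed_features_2d(f, lab, seed = 4)
  expect_identical(nrow(emb), 60L)
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(lab + 1L, stats::dist(cbind(emb$x, emb$y)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  emb2 <- embed_features_2d(f, lab, seed = 4)
  expect_identical(emb, emb2)
  expect_error(embed_features_2d(matrix(1, 10, 3), rep(0, 10)), "constant")
  expect_error(embed_features_2d(f[1:3, ], lab[1:3]), "at least 5")
})
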