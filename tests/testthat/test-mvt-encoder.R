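# Token calculus of the transformer branch: patch embedding, cross-view
# attention, encoder blocks, and the assembled branch forward.

test_that("patch embedding yields (N+1) tokens with additive positional term", {
  img <- array(runif(224 * 224 * 3), c(224, 224, 3))
  tok <- patch_embed(img, Q = 16, d = 32)
  expect_identical(dim(tok), c(197L, 32L))     # (224/16)^2 + class token
  # every token row has length d
  expect_identical(ncol(patch_embed(img, 16, 8)), 8L)
  # positional embedding enters purely additively
  q <- matrix(rnorm(197 * 32), 197, 32)
  expect_equal(patch_embed(img, 16, 32, pos = q) - tok, q)
  expect_error(patch_embed(img, Q = 15, d = 8), "divisible")
})

test_that("cross-view attention is row-stochastic and matches hand arithmetic", {
  set.seed(5)
  x <- matrix(rnorm(12), 4, 3)
  y <- matrix(rnorm(15), 5, 3)
  out <- cross_view_attention(x, y)
  a <- attr(out, "attention")
  expect_equal(rowSums(a), rep(1, 4))
  # a single key/value token forces attention weight 1: output = Zv y
  y1 <- matrix(rnorm(3), 1, 3)
  o1 <- cross_view_attention(x, y1)
  expect_equal(o1, matrix(rep(y1, each = 4), 4, 3), ignore_attr = TRUE)
  # 2-token hand example with identity projections and d_k = 1
  xh <- matrix(c(1, 0), 1, 2)
  yh <- rbind(c(1, 0), c(0, 1))
  oh <- cross_view_attention(xh, yh, d_k = 1)
  w <- exp(1) / (exp(1) + 1)
  expect_equal(attr(oh, "attention")[1, ], c(w, 1 - w))
  expect_equal(as.vector(oh), c(w, 1 - w))
})

test_that("adjacent-view fusion projects, preserves query length, and matches brute force", {
  set.seed(6)
  A_i <- matrix(rnorm(6 * 2), 6, 2)
  A_i1 <- matrix(rnorm(6 * 4), 6, 4)
  Zp <- matrix(rnorm(8), 4, 2)
  out <- fuse_adjacent_views(A_i, A_i1, Zp)
  expect_identical(dim(out), c(6L, 2L))
  # identity projection on equal dims reduces to plain cross-view attention
  B <- matrix(rnorm(12), 6, 2)
  expect_equal(fuse_adjacent_views(A_i, B),
               cross_view_attention(A_i, B))
  # brute-force oracle: explicit softmax of projected scores
  yp <- A_i1 %*% Zp
  s <- A_i %*% t(yp) / sqrt(2)
  a <- exp(s) / rowSums(exp(s))
  expect_equal(unclass(out), a %*% yp, ignore_attr = TRUE)
  expect_error(fuse_adjacent_views(A_i, A_i1), "Z_proj")
})

test_that("encoder block is a pre-norm residual map, identity when output weights vanish", {
  set.seed(7)
  w <- encoder_block_weights(4, heads = 2, mlp_ratio = 2)
  A <- matrix(rnorm(12), 3, 4)
  out <- global_encoder_block(A, w)
  expect_identical(dim(out), dim(A))          # shape preserved
  w0 <- w
  w0$Wo <- w0$Wo * 0
  w0$W2 <- w0$W2 * 0
  expect_equal(global_encoder_block(A, w0), A)  # pure residual path
  # single-head numeric oracle on a (2, 2) toy with fixed weights
  wt <- list(ln1_g = c(1, 1), ln1_b = c(0, 0),
             Wq = diag(2), Wk = diag(2), Wv = diag(2), Wo = diag(2),
             ln2_g = c(1, 1), ln2_b = c(0, 0),
             W1 = diag(2), W2 = diag(2), heads = 1L)
  A2 <- rbind(c(1, -1), c(2, 0))
  lnorm <- function(m) {
    mu <- rowMeans(m); s <- sqrt(rowMeans(m * m) - mu^2 + 1e-5)
    (m - mu) / s
  }
  h <- lnorm(A2)
  s <- h %*% t(h) / sqrt(2)
  a <- exp(s - apply(s, 1, max)); a <- a / rowSums(a)
  y <- A2 + a %*% h
  h2 <- lnorm(y)
  gelu <- function(z) z * pnorm(z)
  expect_equal(global_encoder_block(A2, wt), y + gelu(h2))
})

test_that("branch forward has the printed tap shape and no cross-sample mixing", {
  s <- shapes_224()
  expect_identical(feature_map_shape(s$mvt), c(512L, 14L, 14L))
  expect_identical(dim(s$mvt$logits), c(1L, 8L))

  ns <- asNamespace("ofml")
  set.seed(8)
  model <- ns$make_mvt(4, image_size = 32, patch = 8, view_dims = c(8, 12, 16),
                       layers_per_view = 1, global_depth = 1, heads = 2,
                       mlp_ratio = 2)
  x <- array(runif(2 * 32 * 32 * 3), c(2, 32, 32, 3))
  out <- mvt_forward(model, x)
  expect_identical(dim(out$logits), c(2L, 4L))
  expect_identical(feature_map_shape(out), c(16L, 4L, 4L))
  # permuting the batch permutes the outputs
  xr <- x[c(2, 1), , , , drop = FALSE]
  outr <- mvt_forward(model, xr)
  expect_equal(outr$logits, out$logits[c(2, 1), ], ignore_attr = TRUE)
  expect_equal(outr$feature_map[1, , , ], out$feature_map[2, , , ])
  expect_error(mvt_forward(model, x, tap_layer = 7), "tap layer")
})

test_that("gradients reach the embeddings, positional terms and view projections", {
  ns <- asNamespace("ofml")
  set.seed(9)
  model <- ns$make_mvt(4, image_size = 32, patch = 8, view_dims = c(8, 12, 16),
                       layers_per_view = 1, global_depth = 1, heads = 2,
                       mlp_ratio = 2)
  x <- array(runif(2 * 32 * 32 * 3), c(2, 32, 32, 3))
  Y <- matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 2, 4, byrow = TRUE)
  out <- ns$mvt_fwd(model, x)
  ns$ag_backward(ns$ce_node(out$logits, Y))
  gn <- function(p) if (is.null(p$grad)) 0 else sqrt(sum(p$grad^2))
  for (v in seq_along(model$views)) {
    expect_gt(gn(model$views[[v]]$E$W), 0)
    expect_gt(gn(model$views[[v]]$pos), 0)
    expect_gt(gn(model$views[[v]]$cls), 0)
  }
  for (cv in model$cvas) {
    expect_gt(gn(cv$proj$W), 0)
    expect_gt(gn(cv$zq$W), 0)
  }
  ns$zero_grads(ns$collect_params(model))
})
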