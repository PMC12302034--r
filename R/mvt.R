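# Multi-view transformer branch.
#
# Each "view" is an independent transformer encoder over the same patch
# sequence, with its own patch embedding, class token, positional embedding
# and hidden dimension. Adjacent views are fused by cross-view attention
# (CVA): queries come from view i, keys/values from view i+1 after a learned
# projection to view i's width. Fusion cascades from the deepest view down
# (fused_n = A^(n); fused_i = CVA(A^(i), Z_proj_i fused_{i+1})) so that every
# view's parameters receive gradient, and the final fused sequence enters a
# global pre-norm encoder whose class token feeds the classification head.
# The tapped intermediate feature map is a view encoder's patch tokens
# reshaped to a spatial grid (view 3: 512 channels, 14x14 at 224 px).

make_mvt <- function(num_classes, image_size, patch = 16L,
                     view_dims = c(256L, 384L, 512L), layers_per_view = 4L,
                     global_depth = 4L, heads = 8L, mlp_ratio = 4L,
                     multi_view = TRUE, tap_layer = 3L) {
  if (image_size %% patch != 0L) {
    stop("image_size must be divisible by the patch size")
  }
  if (!multi_view) view_dims <- view_dims[length(view_dims)]
  if (multi_view && length(view_dims) < 2L) {
    stop("multi-view encoding needs at least 2 views")
  }
  tap_layer <- as.integer(tap_layer)
  if (tap_layer > length(view_dims)) {
    stop("tap_layer exceeds the number of views")
  }
  side <- image_size %/% patch
  np <- side * side
  t <- np + 1L
  pdim <- patch * patch * 3L
  xav <- function(fin, fout) sqrt(2 / (fin + fout))
  views <- lapply(view_dims, function(d) {
    list(E = lin_init(pdim, d, sd = xav(pdim, d), bias = FALSE),
         cls = ag_param(matrix(stats::rnorm(d, 0, 0.02), 1L, d)),
         pos = ag_param(matrix(stats::rnorm(t * d, 0, 0.02), t, d)),
         layers = lapply(seq_len(layers_per_view), function(j) {
           encoder_layer_init(d, heads, mlp_ratio)
         }))
  })
  cvas <- NULL
  if (multi_view) {
    cvas <- lapply(seq_len(length(view_dims) - 1L), function(i) {
      di <- view_dims[i]; dj <- view_dims[i + 1L]
      list(proj = lin_init(dj, di, sd = xav(dj, di), bias = FALSE),
           zq = lin_init(di, di, sd = sqrt(1 / di), bias = FALSE),
           zk = lin_init(di, di, sd = sqrt(1 / di), bias = FALSE),
           zv = lin_init(di, di, sd = sqrt(1 / di), bias = FALSE))
    })
  }
  gd <- view_dims[1L]
  structure(list(
    views = views, cvas = cvas,
    global = lapply(seq_len(global_depth), function(j) {
      encoder_layer_init(gd, heads, mlp_ratio)
    }),
    ln_f = ln_init(gd),
    head = lin_init(gd, num_classes, sd = sqrt(1 / gd)),
    patch = as.integer(patch), side = as.integer(side), np = np, t = t,
    view_dims = as.integer(view_dims), multi_view = multi_view,
    tap_layer = tap_layer, num_classes = as.integer(num_classes),
    image_size = as.integer(image_size)), class = "mvt_branch")
}

cva_fwd <- function(xseq, yseq, cv, nb, tx, ty) {
  yp <- ag_mm(yseq, cv$proj$W)
  di <- ncol(cv$zq$W$value)
  ag_attention(ag_mm(xseq, cv$zq$W), ag_mm(yp, cv$zk$W), ag_mm(yp, cv$zv$W),
               nb, tx, ty, 1 / sqrt(di))
}

# Forward pass; x is an (N,H,W,3) array (constant). Returns nodes for the
# logits and each view's tapped spatial feature map.
mvt_fwd <- function(model, x, tap_layers = model$tap_layer) {
  xv <- val(x)
  nb <- dim(xv)[1]
  ic <- im2col(xv, model$patch, model$patch, 0L)
  # rows of ic$G are sample-fastest within patch; reorder to sample-major
  perm <- rep(seq_len(nb), each = model$np) +
    nb * (rep(seq_len(model$np), times = nb) - 1L)
  xb <- ic$G[perm, , drop = FALSE]
  t <- model$t
  seqs <- vector("list", length(model$views))
  for (v in seq_along(model$views)) {
    vw <- model$views[[v]]
    tok <- ag_mm(ag_node(xb), vw$E$W)
    tok <- ag_prepend_cls(tok, vw$cls, nb)
    tok <- ag_add_posemb(tok, vw$pos, nb)
    for (lay in vw$layers) tok <- encoder_layer_fwd(tok, lay, nb, t)
    seqs[[v]] <- tok
  }
  nv <- length(seqs)
  fused <- seqs[[nv]]
  if (model$multi_view && nv > 1L) {
    for (i in seq(nv - 1L, 1L)) {
      fused <- cva_fwd(seqs[[i]], fused, model$cvas[[i]], nb, t, t)
    }
  }
  for (lay in model$global) fused <- encoder_layer_fwd(fused, lay, nb, t)
  fused <- ln_fwd(fused, model$ln_f)
  cls_rows <- seq(1L, by = t, length.out = nb)
  logits <- linear_fwd(ag_rows(fused, cls_rows), model$head)
  patch_rows <- setdiff(seq_len(nb * t), cls_rows)
  taps <- list()
  for (v in tap_layers) {
    taps[[as.character(v)]] <- ag_tokens_to_nhwc(
      ag_rows(seqs[[v]], patch_rows), nb, model$side, model$side)
  }
  list(logits = logits, taps = taps)
}

#' Forward pass of the multi-view transformer branch
#'
#' Embeds each image as a sequence of patch tokens, runs the per-view
#' encoders, fuses adjacent views with cross-view attention, and applies the
#' global encoder. Logits come from the class token; the tapped feature map
#' is the chosen view's patch tokens on their spatial grid (the class token
#' is dropped). For 224-px input with the default configuration the tap has
#' per-sample shape (512, 14, 14).
#'
#' @param model A branch built by [make_mvt()], or `NULL` to build the
#'   default for `num_classes` and the batch's image size.
#' @param batch Images as in [cnn_forward()].
#' @param num_classes Number of classes (used only when `model` is `NULL`).
#' @param tap_layer Which view's encoder output to tap (default: the model's
#'   configured tap, view 3).
#' @return A `branch_output` list (`logits`, `feature_map`, `tap_stage`).
#' @export
mvt_forward <- function(model = NULL, batch, num_classes = NULL,
                        tap_layer = NULL) {
  x <- as_image_batch(batch)
  if (is.null(model)) {
    if (is.null(num_classes)) stop("mvt_forward: give a model or num_classes")
    model <- make_mvt(num_classes, image_size = dim(x)[2])
  }
  if (dim(x)[2] != model$image_size || dim(x)[3] != model$image_size) {
    stop("mvt_forward: image size does not match the model configuration")
  }
  tl <- if (is.null(tap_layer)) model$tap_layer else as.integer(tap_layer)
  if (tl > length(model$views)) stop("mvt_forward: tap layer deeper than available views")
  out <- with_no_grad(mvt_fwd(model, x, tap_layers = tl))
  branch_output(val(out$logits), val(out$taps[[as.character(tl)]]), tl)
}

# ---- numeric token-level operations (single sample, plain matrices) --------
# These are direct, tape-free implementations of the token calculus used in
# documentation and tests; the trained model uses the autodiff path above.

#' Patch-token embedding of a single image
#'
#' Splits an `(H, W, 3)` image into non-overlapping `Q x Q` patches, flattens
#' each to a `3*Q^2` vector (row, column, channel order), maps it to dimension
#' `d` with the embedding matrix `E`, prepends a class token and adds a
#' positional embedding, yielding the `(N+1) x d` token sequence that enters a
#' view encoder (`N = (H/Q) * (W/Q)`).
#'
#' @param image `(H, W, 3)` numeric array; `H` and `W` must be divisible by `Q`.
#' @param Q Patch side length in pixels.
#' @param d Embedding dimension.
#' @param E `(3*Q^2) x d` embedding matrix; default is a fixed 0/1
#'   coordinate-selection matrix so the function is deterministic.
#' @param cls_token Length-`d` class token (default zeros).
#' @param pos `(N+1) x d` positional embedding (default zeros).
#' @return `(N+1) x d` matrix; row 1 is the class token.
#' @export
patch_embed <- function(image, Q, d, E = NULL, cls_token = NULL, pos = NULL) {
  dm <- dim(image)
  if (length(dm) != 3L || dm[3] != 3L) stop("image must be (H, W, 3)")
  if (dm[1] %% Q != 0L || dm[2] %% Q != 0L) {
    stop("image sides must be divisible by the patch size Q")
  }
  nh <- dm[1] %/% Q
  nw <- dm[2] %/% Q
  n <- nh * nw
  pdim <- Q * Q * 3L
  if (is.null(E)) {
    E <- matrix(0, pdim, d)
    E[cbind(seq_len(min(pdim, d)), seq_len(min(pdim, d)))] <- 1
  }
  stopifnot(nrow(E) == pdim, ncol(E) == d)
  xp <- matrix(0, n, pdim)
  idx <- 0L
  for (ow in seq_len(nw)) {
    for (oh in seq_len(nh)) {
      idx <- idx + 1L
      patch <- image[((oh - 1L) * Q + 1L):(oh * Q),
                     ((ow - 1L) * Q + 1L):(ow * Q), , drop = FALSE]
      xp[idx, ] <- as.vector(patch)
    }
  }
  tok <- xp %*% E
  if (is.null(cls_token)) cls_token <- numeric(d)
  out <- rbind(matrix(cls_token, 1L, d), tok)
  if (!is.null(pos)) {
    stopifnot(nrow(pos) == n + 1L, ncol(pos) == d)
    out <- out + pos
  }
  out
}

#' Cross-view attention between two token sequences
#'
#' Queries are projected from `x_seq`, keys and values from `y_seq`:
#' `softmax(Zq x (Zk y)' / sqrt(d_k)) Zv y`. Each row of the attention matrix
#' sums to one.
#'
#' @param x_seq `(Tx, dx)` query-side token matrix.
#' @param y_seq `(Ty, dy)` key/value-side token matrix.
#' @param Zq,Zk,Zv Projection matrices (`dx x d_k`, `dy x d_k`, `dy x d_v`);
#'   identity by default (requires `dx == dy`).
#' @param d_k Key dimension used in the `1/sqrt(d_k)` score scaling; defaults
#'   to the projected key width.
#' @return `(Tx, d_v)` matrix with the attention matrix in
#'   `attr(, "attention")`.
#' @export
cross_view_attention <- function(x_seq, y_seq, Zq = NULL, Zk = NULL, Zv = NULL,
                                 d_k = NULL) {
  x_seq <- as.matrix(x_seq); y_seq <- as.matrix(y_seq)
  if (is.null(Zq)) Zq <- diag(ncol(x_seq))
  if (is.null(Zk)) Zk <- diag(ncol(y_seq))
  if (is.null(Zv)) Zv <- diag(ncol(y_seq))
  q <- x_seq %*% Zq
  k <- y_seq %*% Zk
  v <- y_seq %*% Zv
  if (ncol(q) != ncol(k)) stop("projected query/key dimensions differ")
  if (is.null(d_k)) d_k <- ncol(k)
  s <- q %*% t(k) / sqrt(d_k)
  s <- exp(s - apply(s, 1L, max))
  a <- s / rowSums(s)
  structure(a %*% v, attention = a)
}

#' Fuse two adjacent view sequences
#'
#' Applies cross-view attention with queries from view `i` and keys/values
#' from view `i+1` after projecting the latter to view `i`'s width:
#' `CVA(A_i, Z_proj A_{i+1})`. The output keeps view `i`'s sequence length
#' and dimension.
#'
#' @param A_i `(T, d_i)` view-`i` sequence.
#' @param A_i1 `(T, d_{i+1})` view-`(i+1)` sequence.
#' @param Z_proj `d_{i+1} x d_i` projection; identity when the dims agree and
#'   `Z_proj` is omitted.
#' @param Zq,Zk,Zv Optional attention projections (identity by default).
#' @return `(T, d_i)` fused sequence.
#' @export
fuse_adjacent_views <- function(A_i, A_i1, Z_proj = NULL, Zq = NULL,
                                Zk = NULL, Zv = NULL) {
  A_i <- as.matrix(A_i); A_i1 <- as.matrix(A_i1)
  if (is.null(Z_proj)) {
    if (ncol(A_i) != ncol(A_i1)) {
      stop("Z_proj is required when the view dimensions differ")
    }
    Z_proj <- diag(ncol(A_i1))
  }
  if (nrow(Z_proj) != ncol(A_i1) || ncol(Z_proj) != ncol(A_i)) {
    stop("Z_proj must map the view-(i+1) dimension to the view-i dimension")
  }
  cross_view_attention(A_i, A_i1 %*% Z_proj, Zq, Zk, Zv)
}

#' One pre-norm global encoder block
#'
#' Computes `y = MSA(LN(A)) + A` followed by `A' = MLP(LN(y)) + y`, where the
#' MLP is two linear maps with a GELU between them. With the attention and
#' MLP output weights zeroed the block is the identity map.
#'
#' @param A_prev `(T, d)` token matrix.
#' @param weights List from [encoder_block_weights()] (or with the same
#'   fields).
#' @return `(T, d)` token matrix.
#' @export
global_encoder_block <- function(A_prev, weights) {
  w <- weights
  x <- as.matrix(A_prev)
  lnorm <- function(m, g, b) {
    mu <- rowMeans(m)
    sd <- sqrt(rowMeans(m * m) - mu * mu + 1e-5)
    sweep(sweep((m - mu) / sd, 2L, g, "*"), 2L, b, "+")
  }
  h <- lnorm(x, w$ln1_g, w$ln1_b)
  d <- ncol(x)
  heads <- w$heads
  dh <- d %/% heads
  q <- h %*% w$Wq; k <- h %*% w$Wk; v <- h %*% w$Wv
  att <- matrix(0, nrow(x), d)
  for (hd in seq_len(heads)) {
    cols <- ((hd - 1L) * dh + 1L):(hd * dh)
    s <- q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE]) / sqrt(dh)
    s <- exp(s - apply(s, 1L, max))
    a <- s / rowSums(s)
    att[, cols] <- a %*% v[, cols, drop = FALSE]
  }
  y <- x + att %*% w$Wo
  h2 <- lnorm(y, w$ln2_g, w$ln2_b)
  gelu <- function(z) z * stats::pnorm(z)
  y + gelu(h2 %*% w$W1) %*% w$W2
}

#' Random weights for a numeric encoder block
#'
#' @param d Token dimension. @param heads Attention heads. @param mlp_ratio
#'   Hidden-layer expansion of the MLP.
#' @return A list of matrices/vectors consumed by [global_encoder_block()].
#' @export
encoder_block_weights <- function(d, heads = 1L, mlp_ratio = 2L) {
  r <- function(a, b) matrix(stats::rnorm(a * b, 0, sqrt(2 / (a + b))), a, b)
  list(ln1_g = rep(1, d), ln1_b = numeric(d),
       Wq = r(d, d), Wk = r(d, d), Wv = r(d, d), Wo = r(d, d),
       ln2_g = rep(1, d), ln2_b = numeric(d),
       W1 = r(d, d * mlp_ratio), W2 = r(d * mlp_ratio, d),
       heads = as.integer(heads))
}
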