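# Reverse-mode automatic differentiation over dense arrays.
#
# A node is an environment holding a value, an accumulated gradient, its
# parents and a backward closure. Creation order gives a valid topological
# order, so backward() walks ids in decreasing order. Gradients are only
# propagated into subgraphs that contain parameters.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L
.ag$grad_enabled <- TRUE
.ag$cache <- new.env(parent = emptyenv())

ag_next_id <- function() {
  .ag$id <- .ag$id + 1L
  .ag$id
}

ag_node <- function(value, parents = list(), backfn = NULL, extra = NULL) {
  requires <- .ag$grad_enabled && length(parents) > 0L &&
    any(vapply(parents, function(p) isTRUE(p$requires), logical(1)))
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- if (requires) parents else list()
  e$backfn <- if (requires) backfn else NULL
  e$requires <- requires
  e$extra <- extra
  e$id <- ag_next_id()
  class(e) <- "ag_node"
  e
}

# Trainable parameter: a leaf node that also carries Adam state.
ag_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- list()
  e$backfn <- NULL
  e$requires <- TRUE
  e$id <- ag_next_id()
  e$m <- NULL
  e$v <- NULL
  class(e) <- c("ag_param", "ag_node")
  e
}

is_node <- function(x) inherits(x, "ag_node")
as_node <- function(x) if (is_node(x)) x else ag_node(x)
val <- function(x) if (is_node(x)) x$value else x

with_no_grad <- function(expr) {
  old <- .ag$grad_enabled
  .ag$grad_enabled <- FALSE
  on.exit(.ag$grad_enabled <- old)
  force(expr)
}

ag_backward <- function(root) {
  stopifnot(is_node(root))
  if (!isTRUE(root$requires)) return(invisible(root))
  nodes <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack) > 0L) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) {
      if (isTRUE(p$requires)) stack[[length(stack) + 1L]] <- p
    }
  }
  ids <- vapply(nodes, function(n) n$id, integer(1))
  v0 <- root$value
  root$grad <- if (length(v0) == 1L) 1 else array(1, dim = dim(v0))
  for (i in order(ids, decreasing = TRUE)) {
    n <- nodes[[i]]
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    ps <- n$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!isTRUE(p$requires)) next
      g <- gs[[j]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# ---- elementary operations (matrices / arrays) ------------------------------

ag_mm <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  ag_node(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

ag_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# elementwise product with a constant array
ag_cmul <- function(a, m) {
  a <- as_node(a)
  ag_node(a$value * m, list(a), function(g) list(g * m))
}

ag_scale <- function(a, s) {
  a <- as_node(a)
  ag_node(a$value * s, list(a), function(g) list(g * s))
}

ag_add_bias <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  bv <- b$value
  out <- a$value + matrix(bv, nrow(a$value), length(bv), byrow = TRUE)
  ag_node(out, list(a, b), function(g) list(g, colSums(g)))
}

ag_relu <- function(a) {
  a <- as_node(a)
  mask <- a$value > 0
  ag_node(a$value * mask, list(a), function(g) list(g * mask))
}

ag_gelu <- function(a) {
  a <- as_node(a)
  x <- a$value
  ph <- stats::pnorm(x)
  ag_node(x * ph, list(a), function(g) list(g * (ph + x * stats::dnorm(x))))
}

ag_log <- function(a, eps = 1e-12) {
  a <- as_node(a)
  xc <- pmax(a$value, eps)
  ag_node(log(xc), list(a), function(g) list(g / xc))
}

ag_softmax_rows <- function(a) {
  a <- as_node(a)
  x <- a$value
  s <- exp(x - apply(x, 1L, max))
  s <- s / rowSums(s)
  ag_node(s, list(a), function(g) {
    list((g - rowSums(g * s)) * s)
  })
}

ag_sum <- function(a) {
  a <- as_node(a)
  av <- a$value
  dm <- dim(av)
  ag_node(sum(av), list(a), function(g) {
    list(if (is.null(dm)) rep(g, length(av)) else array(g, dim = dm))
  })
}

ag_mean <- function(a) {
  a <- as_node(a)
  av <- a$value
  dm <- dim(av)
  n <- length(av)
  ag_node(mean(av), list(a), function(g) {
    list(if (is.null(dm)) rep(g / n, n) else array(g / n, dim = dm))
  })
}

ag_detach <- function(a) ag_node(val(a))

ag_concat_cols <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  na <- ncol(a$value)
  ag_node(cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

ag_rows <- function(a, idx) {
  a <- as_node(a)
  av <- a$value
  ag_node(av[idx, , drop = FALSE], list(a), function(g) {
    z <- matrix(0, nrow(av), ncol(av))
    z[idx, ] <- g
    list(z)
  })
}

ag_cols <- function(a, idx) {
  a <- as_node(a)
  av <- a$value
  ag_node(av[, idx, drop = FALSE], list(a), function(g) {
    z <- matrix(0, nrow(av), ncol(av))
    z[, idx] <- g
    list(z)
  })
}

ag_permute_rows <- function(a, perm) {
  a <- as_node(a)
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  ag_node(a$value[perm, , drop = FALSE], list(a), function(g) {
    list(g[inv, , drop = FALSE])
  })
}

# ---- attention --------------------------------------------------------------

# Scaled dot-product attention over a batch of token blocks.
# q: (nb*tq, dk), k: (nb*tk, dk), v: (nb*tk, dv), rows sample-major.
# Returns (nb*tq, dv); attention matrices retained in $extra$attn.
ag_attention <- function(q, k, v, nb, tq, tk, scale) {
  q <- as_node(q); k <- as_node(k); v <- as_node(v)
  qv <- q$value; kv <- k$value; vv <- v$value
  out <- matrix(0, nb * tq, ncol(vv))
  attn <- vector("list", nb)
  for (b in seq_len(nb)) {
    rq <- ((b - 1L) * tq + 1L):(b * tq)
    rk <- ((b - 1L) * tk + 1L):(b * tk)
    s <- (qv[rq, , drop = FALSE] %*% t(kv[rk, , drop = FALSE])) * scale
    s <- exp(s - apply(s, 1L, max))
    a <- s / rowSums(s)
    out[rq, ] <- a %*% vv[rk, , drop = FALSE]
    attn[[b]] <- a
  }
  ag_node(out, list(q, k, v), function(g) {
    dq <- matrix(0, nrow(qv), ncol(qv))
    dk <- matrix(0, nrow(kv), ncol(kv))
    dv <- matrix(0, nrow(vv), ncol(vv))
    for (b in seq_len(nb)) {
      rq <- ((b - 1L) * tq + 1L):(b * tq)
      rk <- ((b - 1L) * tk + 1L):(b * tk)
      a <- attn[[b]]
      gb <- g[rq, , drop = FALSE]
      vi <- vv[rk, , drop = FALSE]
      dv[rk, ] <- dv[rk, ] + crossprod(a, gb)
      da <- gb %*% t(vi)
      ds <- (da - rowSums(da * a)) * a
      dq[rq, ] <- dq[rq, ] + ds %*% kv[rk, , drop = FALSE] * scale
      dk[rk, ] <- dk[rk, ] + crossprod(ds, qv[rq, , drop = FALSE]) * scale
    }
    list(dq, dk, dv)
  }, extra = list(attn = attn))
}

# ---- convolution / pooling --------------------------------------------------

# im2col index cache, keyed by (H, W, C, k, stride, pad). Weight layout for a
# k x k x Cin -> Cout convolution is a (k*k*Cin, Cout) matrix with rows ordered
# kh fastest, then kw, then channel (native R array order of (k, k, Cin)).
conv_meta <- function(H, W, C, k, s, p) {
  key <- paste(H, W, C, k, s, p, sep = "x")
  m <- .ag$cache[[key]]
  if (!is.null(m)) return(m)
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  OH <- (Hp - k) %/% s + 1L
  OW <- (Wp - k) %/% s + 1L
  ohw <- OH * OW
  kkc <- k * k * C
  ohv <- rep(seq_len(OH), times = OW)
  owv <- rep(seq_len(OW), each = OH)
  khv <- rep(seq_len(k), times = k * C)
  kwv <- rep(rep(seq_len(k), each = k), times = C)
  ccv <- rep(seq_len(C), each = k * k)
  hh <- rep((ohv - 1L) * s, times = kkc) + rep(khv, each = ohw)
  ww <- rep((owv - 1L) * s, times = kkc) + rep(kwv, each = ohw)
  cc <- rep(ccv, each = ohw)
  idx <- hh + Hp * (ww - 1L) + Hp * Wp * (cc - 1L)
  m <- new.env(parent = emptyenv())
  m$idx <- idx
  m$Hp <- Hp; m$Wp <- Wp; m$OH <- OH; m$OW <- OW
  m$kkc <- kkc; m$H <- H; m$W <- W; m$C <- C; m$p <- p
  m$S <- NULL
  assign(key, m, envir = .ag$cache)
  m
}

conv_scatter <- function(m) {
  if (is.null(m$S)) {
    L <- length(m$idx)
    m$S <- Matrix::sparseMatrix(i = seq_len(L), j = m$idx, x = 1,
                                dims = c(L, m$Hp * m$Wp * m$C))
  }
  m$S
}

pad_nhwc <- function(x, p, fill = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(fill, c(d[1], d[2] + 2L * p, d[3] + 2L * p, d[4]))
  out[, (p + 1L):(p + d[2]), (p + 1L):(p + d[3]), ] <- x
  out
}

# columns of the im2col matrix for x (N,H,W,C): returns (N*OH*OW, k*k*C)
im2col <- function(x, k, s, p) {
  d <- dim(x)
  N <- d[1]
  m <- conv_meta(d[2], d[3], d[4], k, s, p)
  P <- pad_nhwc(x, p)
  dim(P) <- c(N, m$Hp * m$Wp * m$C)
  G <- P[, m$idx, drop = FALSE]
  dim(G) <- c(N * m$OH * m$OW, m$kkc)
  list(G = G, meta = m, N = N)
}

ag_conv2d <- function(x, w, b = NULL, k, stride = 1L, pad = 0L) {
  x <- as_node(x)
  xv <- x$value
  ic <- im2col(xv, k, stride, pad)
  G <- ic$G; m <- ic$meta; N <- ic$N
  wv <- w$value
  Y <- G %*% wv
  if (!is.null(b)) Y <- Y + matrix(b$value, nrow(Y), length(b$value), byrow = TRUE)
  cout <- ncol(wv)
  dim(Y) <- c(N, m$OH, m$OW, cout)
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  ag_node(Y, parents, function(g) {
    dim(g) <- c(N * m$OH * m$OW, cout)
    dW <- crossprod(G, g)
    db <- if (!is.null(b)) colSums(g) else NULL
    dx <- NULL
    if (isTRUE(x$requires)) {
      dG <- tcrossprod(g, wv)
      dim(dG) <- c(N, m$OH * m$OW * m$kkc)
      dP <- as.matrix(dG %*% conv_scatter(m))
      dim(dP) <- c(N, m$Hp, m$Wp, m$C)
      dx <- if (m$p > 0L) {
        dP[, (m$p + 1L):(m$p + m$H), (m$p + 1L):(m$p + m$W), , drop = FALSE]
      } else dP
    }
    c(list(dx, dW), if (!is.null(b)) list(db))
  })
}

ag_maxpool2d <- function(x, k = 3L, stride = 2L, pad = 1L) {
  x <- as_node(x)
  xv <- x$value
  d <- dim(xv)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  m <- conv_meta(H, W, 1L, k, stride, pad)
  P <- pad_nhwc(xv, pad, fill = -Inf)
  xp <- aperm(P, c(1, 4, 2, 3))
  NC <- N * C
  dim(xp) <- c(NC, m$Hp * m$Wp)
  G <- xp[, m$idx, drop = FALSE]
  ohw <- m$OH * m$OW
  kk <- k * k
  dim(G) <- c(NC * ohw, kk)
  amax <- max.col(G, ties.method = "first")
  v <- G[cbind(seq_len(nrow(G)), amax)]
  out <- v
  dim(out) <- c(NC, m$OH, m$OW)
  dim(out) <- c(N, C, m$OH, m$OW)
  out <- aperm(out, c(1, 3, 4, 2))
  ag_node(out, list(x), function(g) {
    gp <- aperm(g, c(1, 4, 2, 3))
    gv <- as.vector(gp)                       # rows r = (nc, ohw)
    r <- seq_along(gv)
    ohw_of <- (r - 1L) %/% NC + 1L
    nc_of <- (r - 1L) %% NC + 1L
    pcol <- m$idx[ohw_of + ohw * (amax - 1L)]
    key <- nc_of + NC * (pcol - 1L)
    acc <- rowsum(gv, key)
    dM <- matrix(0, NC, m$Hp * m$Wp)
    dM[as.integer(rownames(acc))] <- acc
    dim(dM) <- c(N, C, m$Hp, m$Wp)
    dP <- aperm(dM, c(1, 3, 4, 2))
    list(if (pad > 0L) {
      dP[, (pad + 1L):(pad + H), (pad + 1L):(pad + W), , drop = FALSE]
    } else dP)
  })
}

# global average pooling (N,H,W,C) -> (N,C)
ag_gap2d <- function(x) {
  x <- as_node(x)
  xv <- x$value
  d <- dim(xv)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  xp <- aperm(xv, c(1, 4, 2, 3))
  dim(xp) <- c(N * C, H * W)
  out <- matrix(rowMeans(xp), N, C)
  ag_node(out, list(x), function(g) {
    dxp <- matrix(as.vector(g) / (H * W), N * C, H * W)
    dim(dxp) <- c(N, C, H, W)
    list(aperm(dxp, c(1, 3, 4, 2)))
  })
}

# ---- normalization ----------------------------------------------------------

ag_bn2d <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  x <- as_node(x)
  xv <- x$value
  d <- dim(xv)
  C <- d[4]
  xm <- xv
  dim(xm) <- c(prod(d[1:3]), C)
  n <- nrow(xm)
  gv <- gamma$value; bv <- beta$value
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va * n / max(1, n - 1)
  } else {
    mu <- state$mean
    va <- state$var
  }
  isd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, isd, "*")
  y <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  dim(y) <- d
  ag_node(y, list(x, gamma, beta), function(g) {
    gm <- g
    dim(gm) <- c(n, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxh <- sweep(gm, 2L, gv, "*")
    if (training) {
      dxm <- sweep(
        dxh - matrix(colMeans(dxh), n, C, byrow = TRUE) -
          xhat * matrix(colMeans(dxh * xhat), n, C, byrow = TRUE),
        2L, isd, "*")
    } else {
      dxm <- sweep(dxh, 2L, isd, "*")
    }
    dim(dxm) <- d
    list(dxm, dgamma, dbeta)
  })
}

# row-wise layer normalization of a (rows, d) matrix
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x)
  xm <- x$value
  dd <- ncol(xm)
  mu <- rowMeans(xm)
  va <- rowMeans(xm * xm) - mu * mu
  isd <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * isd
  gv <- gamma$value; bv <- beta$value
  y <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  ag_node(y, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxh <- sweep(g, 2L, gv, "*")
    dx <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * isd
    list(dx, dgamma, dbeta)
  })
}

# ---- token-sequence helpers -------------------------------------------------

# prepend one learnable class-token row to each sample block
ag_prepend_cls <- function(x, cls, nb) {
  x <- as_node(x)
  xv <- x$value
  np <- nrow(xv) / nb
  t <- np + 1L
  dd <- ncol(xv)
  pos_cls <- seq(1L, by = t, length.out = nb)
  out <- matrix(0, nb * t, dd)
  out[pos_cls, ] <- matrix(cls$value, nb, dd, byrow = TRUE)
  out[-pos_cls, ] <- xv
  ag_node(out, list(x, cls), function(g) {
    list(g[-pos_cls, , drop = FALSE],
         matrix(colSums(g[pos_cls, , drop = FALSE]), 1L))
  })
}

# add a learnable positional embedding (t, d) to every sample block
ag_add_posemb <- function(x, pos, nb) {
  x <- as_node(x)
  t <- nrow(pos$value)
  grp <- rep(seq_len(t), nb)
  out <- x$value + pos$value[grp, , drop = FALSE]
  ag_node(out, list(x, pos), function(g) {
    list(g, rowsum(g, grp))
  })
}

# sample-major patch tokens (nb*np, d) -> spatial feature map (nb, hh, ww, d);
# patch order within a sample is row-of-grid fastest, matching im2col.
ag_tokens_to_nhwc <- function(x, nb, hh, ww) {
  x <- as_node(x)
  xv <- x$value
  np <- hh * ww
  dd <- ncol(xv)
  y <- aperm(array(xv, c(np, nb, dd)), c(2, 1, 3))
  dim(y) <- c(nb, hh, ww, dd)
  ag_node(y, list(x), function(g) {
    dim(g) <- c(nb, np, dd)
    gm <- aperm(g, c(2, 1, 3))
    dim(gm) <- c(np * nb, dd)
    list(gm)
  })
}

# ---- optimizer --------------------------------------------------------------

collect_params <- function(x) {
  out <- list()
  rec <- function(v) {
    if (inherits(v, "ag_param")) {
      out[[length(out) + 1L]] <<- v
    } else if (is.list(v)) {
      for (e in v) rec(e)
    }
  }
  rec(x)
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

adam_step <- function(params, lr, beta1 = 0.8, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0, t = 1L) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$value
    if (is.null(p$m)) {
      p$m <- g * 0
      p$v <- g * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    p$value <- p$value - lr * (p$m / c1) / (sqrt(p$v / c2) + eps)
  }
  invisible(NULL)
}
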