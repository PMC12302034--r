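# Layer constructors. Each returns a plain list of ag_param objects (plus
# static metadata); collect_params() walks these lists when optimizing.

lin_init <- function(fin, fout, sd = sqrt(2 / fin), bias = TRUE) {
  list(W = ag_param(matrix(stats::rnorm(fin * fout, 0, sd), fin, fout)),
       b = if (bias) ag_param(numeric(fout)) else NULL)
}

linear_fwd <- function(x, l) {
  y <- ag_mm(x, l$W)
  if (!is.null(l$b)) y <- ag_add_bias(y, l$b)
  y
}

conv_init <- function(k, cin, cout, bias = FALSE) {
  fan <- k * k * cin
  list(W = ag_param(matrix(stats::rnorm(fan * cout, 0, sqrt(2 / fan)), fan, cout)),
       b = if (bias) ag_param(numeric(cout)) else NULL,
       k = as.integer(k))
}

conv_fwd <- function(x, l, stride = 1L, pad = 0L) {
  ag_conv2d(x, l$W, l$b, k = l$k, stride = stride, pad = pad)
}

bn_init <- function(c) {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(c)
  st$var <- rep(1, c)
  list(gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c)), state = st)
}

bn_fwd <- function(x, l, training) {
  ag_bn2d(x, l$gamma, l$beta, l$state, training = training)
}

ln_init <- function(d) {
  list(gamma = ag_param(rep(1, d)), beta = ag_param(numeric(d)))
}

ln_fwd <- function(x, l) ag_layernorm(x, l$gamma, l$beta)

# Pre-norm transformer encoder block (multi-head self-attention + GELU MLP).
encoder_layer_init <- function(d, heads, mlp_ratio = 4L) {
  xav <- function(fin, fout) sqrt(2 / (fin + fout))
  stopifnot(d %% heads == 0L)
  list(ln1 = ln_init(d),
       wq = lin_init(d, d, sd = xav(d, d)),
       wk = lin_init(d, d, sd = xav(d, d)),
       wv = lin_init(d, d, sd = xav(d, d)),
       wo = lin_init(d, d, sd = xav(d, d)),
       ln2 = ln_init(d),
       f1 = lin_init(d, d * mlp_ratio, sd = xav(d, d * mlp_ratio)),
       f2 = lin_init(d * mlp_ratio, d, sd = xav(d * mlp_ratio, d)),
       d = d, heads = as.integer(heads))
}

encoder_layer_fwd <- function(x, lay, nb, t, record_attn = NULL) {
  h <- ln_fwd(x, lay$ln1)
  q <- linear_fwd(h, lay$wq)
  k <- linear_fwd(h, lay$wk)
  v <- linear_fwd(h, lay$wv)
  dh <- lay$d %/% lay$heads
  outs <- vector("list", lay$heads)
  for (hd in seq_len(lay$heads)) {
    cols <- ((hd - 1L) * dh + 1L):(hd * dh)
    outs[[hd]] <- ag_attention(ag_cols(q, cols), ag_cols(k, cols),
                               ag_cols(v, cols), nb, t, t, 1 / sqrt(dh))
    if (!is.null(record_attn)) {
      record_attn[[length(record_attn) + 1L]] <- outs[[hd]]$extra$attn
    }
  }
  att <- outs[[1L]]
  if (lay$heads > 1L) {
    for (hd in 2L:lay$heads) att <- ag_concat_cols(att, outs[[hd]])
  }
  y <- ag_add(x, linear_fwd(att, lay$wo))
  h2 <- ln_fwd(y, lay$ln2)
  ag_add(y, linear_fwd(ag_gelu(linear_fwd(h2, lay$f1)), lay$f2))
}
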