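# Gradient correctness of the reverse-mode core, checked against central
# finite differences on small shapes.

ns <- asNamespace("ofml")

fd_check <- function(make_loss, param, h = 1e-5) {
  ns$zero_grads(list(param))
  ns$ag_backward(make_loss())
  ga <- param$grad
  gn <- ga * 0
  v0 <- param$value
  for (i in seq_along(v0)) {
    param$value[i] <- v0[i] + h
    lp <- ns$val(ns$with_no_grad(make_loss()))
    param$value[i] <- v0[i] - h
    lm <- ns$val(ns$with_no_grad(make_loss()))
    param$value[i] <- v0[i]
    gn[i] <- (lp - lm) / (2 * h)
  }
  ns$zero_grads(list(param))
  max(abs(ga - gn))
}

test_that("convolution, pooling and normalization gradients match finite differences", {
  set.seed(42)
  w <- ns$ag_param(matrix(rnorm(27 * 4, 0, 0.5), 27, 4))
  b <- ns$ag_param(rnorm(4))
  xin <- ns$ag_param(array(rnorm(2 * 6 * 6 * 3, 0, 0.4), c(2, 6, 6, 3)))
  conv_loss <- function() {
    ns$ag_sum(ns$ag_relu(ns$ag_conv2d(xin, w, b, 3L, 1L, 1L)))
  }
  expect_lt(fd_check(conv_loss, w), 1e-6)
  expect_lt(fd_check(conv_loss, b), 1e-6)
  expect_lt(fd_check(conv_loss, xin), 1e-6)

  g <- ns$ag_param(rep(1.2, 3))
  be <- ns$ag_param(rnorm(3))
  st <- new.env(); st$mean <- numeric(3); st$var <- rep(1, 3)
  xb <- ns$ag_param(array(rnorm(2 * 4 * 4 * 3), c(2, 4, 4, 3)))
  noise <- array(rnorm(96), c(2, 4, 4, 3))
  bn_loss <- function() {
    st$mean <- numeric(3); st$var <- rep(1, 3)
    ns$ag_sum(ns$ag_mul(ns$ag_bn2d(xb, g, be, st, training = TRUE),
                        ns$ag_node(noise)))
  }
  expect_lt(fd_check(bn_loss, xb), 1e-6)
  expect_lt(fd_check(bn_loss, g), 1e-6)
  expect_lt(fd_check(bn_loss, be), 1e-6)

  xm <- ns$ag_param(array(rnorm(1 * 6 * 6 * 2), c(1, 6, 6, 2)))
  nz <- array(rnorm(1 * 3 * 3 * 2), c(1, 3, 3, 2))
  mp_loss <- function() {
    ns$ag_sum(ns$ag_mul(ns$ag_maxpool2d(xm, 3L, 2L, 1L), ns$ag_node(nz)))
  }
  expect_lt(fd_check(mp_loss, xm), 1e-6)

  nzg <- matrix(rnorm(2), 1, 2)
  gp_loss <- function() {
    ns$ag_sum(ns$ag_mul(ns$ag_gap2d(xm), ns$ag_node(nzg)))
  }
  expect_lt(fd_check(gp_loss, xm), 1e-6)
})

test_that("attention, layer-norm and loss-node gradients match finite differences", {
  set.seed(43)
  q <- ns$ag_param(matrix(rnorm(6 * 2), 6, 2))
  k <- ns$ag_param(matrix(rnorm(6 * 2), 6, 2))
  v <- ns$ag_param(matrix(rnorm(6 * 3), 6, 3))
  nz <- matrix(rnorm(18), 6, 3)
  at_loss <- function() {
    ns$ag_sum(ns$ag_mul(ns$ag_attention(q, k, v, 2L, 3L, 3L, 1 / sqrt(2)),
                        ns$ag_node(nz)))
  }
  expect_lt(fd_check(at_loss, q), 1e-6)
  expect_lt(fd_check(at_loss, k), 1e-6)
  expect_lt(fd_check(at_loss, v), 1e-6)

  wl <- ns$ag_param(matrix(rnorm(12), 4, 3))
  lg <- ns$ag_param(rep(1, 3))
  lb <- ns$ag_param(rnorm(3))
  nzl <- matrix(rnorm(12), 4, 3)
  ln_loss <- function() {
    ns$ag_sum(ns$ag_mul(ns$ag_layernorm(wl, lg, lb), ns$ag_node(nzl)))
  }
  expect_lt(fd_check(ln_loss, wl), 1e-6)
  expect_lt(fd_check(ln_loss, lg), 1e-6)

  zz <- ns$ag_param(matrix(rnorm(8), 2, 4))
  Y <- matrix(c(1, 0, 0, 0, 0, 0, 1, 0), 2, 4, byrow = TRUE)
  expect_lt(fd_check(function() ns$ce_node(zz, Y), zz), 1e-6)
  tv <- matrix(rnorm(8), 2, 4)
  expect_lt(fd_check(function() ns$kl_student_node(zz, tv, 4), zz), 1e-6)
  expect_lt(fd_check(function() ns$kl_teachee_node(tv, zz, 4), zz), 1e-6)
})

test_that("backward accumulates over shared subexpressions and respects detach", {
  w <- ns$ag_param(matrix(2, 1, 1))
  # y = w*w + w  => dy/dw = 2w + 1 = 5
  y <- ns$ag_add(ns$ag_mul(w, w), w)
  ns$ag_backward(ns$ag_sum(y))
  expect_equal(as.numeric(w$grad), 5)
  ns$zero_grads(list(w))
  # detached branch contributes no gradient
  y2 <- ns$ag_mul(ns$ag_detach(w), w)   # d/dw = const(2)
  ns$ag_backward(ns$ag_sum(y2))
  expect_equal(as.numeric(w$grad), 2)
  ns$zero_grads(list(w))
})
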