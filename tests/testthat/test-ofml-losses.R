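# Softened distributions, cross-entropy, KL transfers, branch and global
# totals — each against closed-form or hand arithmetic.

test_that("soften is a temperature-scaled softmax with the uniform high-T limit", {
  expect_equal(soften(c(0, 0), 3), c(0.5, 0.5))
  expect_equal(soften(c(log(2), 0), 1), c(2 / 3, 1 / 3))
  expect_equal(soften(c(5, -5), 1000), c(0.5, 0.5), tolerance = 1e-2)
  expect_on_simplex(soften(rnorm(6), 4))
  expect_error(soften(c(1, 2), T = 0), "positive")
  # monotone approach to uniform: KL from uniform shrinks as T grows
  z <- c(3, -1, 0.5, 2)
  kls <- vapply(c(1, 2, 4, 8, 16), function(T) {
    kl_divergence(soften(z, T), rep(0.25, 4))
  }, numeric(1))
  expect_true(all(diff(kls) < 0))
})

test_that("cross-entropy matches closed forms for hard and soft labels", {
  expect_equal(cross_entropy(c(1, 0), 0), 0)
  expect_equal(cross_entropy(rep(0.25, 4), 2), log(4))
  # soft Mixup label: -sum(y * log p) on a 2-class toy
  p <- c(0.8, 0.2)
  y <- c(0.5, 0.5)
  expect_equal(cross_entropy(p, y), -0.5 * log(0.8) - 0.5 * log(0.2))
  # batch form averages rows
  P <- rbind(c(0.9, 0.1), c(0.3, 0.7))
  expect_equal(cross_entropy(P, c(0, 1)), mean(-log(c(0.9, 0.7))))
  expect_warning(cross_entropy(c(1, 0), 1), "clamped")
  expect_error(cross_entropy(c(0.7, 0.7), 0), "simplex")
})

test_that("KL divergence matches hand arithmetic and is non-negative everywhere", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3))
  set.seed(12)
  for (i in 1:1000) {
    m <- sample(2:6, 1)
    p <- stats::rgamma(m, 1); p <- p / sum(p)
    q <- stats::rgamma(m, 1); q <- q / sum(q)
    expect_gte(kl_divergence(p, q), 0)
  }
  expect_error(kl_divergence(c(NaN, 1), c(0.5, 0.5)), "non-finite")
})

test_that("branch totals couple supervision with the T^2-weighted fusion transfer", {
  # identical branch and fusion logits: transfer term vanishes
  z <- c(1.2, -0.3)
  bt <- branch_total(z, 0, z, T = 4)
  expect_equal(bt$L_FPKT, 0)
  expect_equal(bt$L_total, bt$L_net)
  # T = 4 multiplies the transfer by exactly 16
  zf <- c(0.5, 0.5)
  bt2 <- branch_total(c(1, -0.5), 0, zf, T = 4)
  expect_equal(bt2$L_total - bt2$L_net, 16 * bt2$L_FPKT)
  # full hand-arithmetic oracle on a 2-class, 1-sample toy
  l_net <- -log(oracle_softmax(c(1, -0.5))[1])
  qs <- oracle_softmax(c(1, -0.5) / 4)
  qt <- oracle_softmax(c(0.5, 0.5) / 4)
  l_fpkt <- sum(qs * log(qs / qt))
  expect_equal(bt2$L_net, l_net, tolerance = 1e-9)
  expect_equal(bt2$L_FPKT, l_fpkt, tolerance = 1e-9)
  expect_equal(bt2$L_total, l_net + 16 * l_fpkt, tolerance = 1e-9)
})

test_that("the global total adds branch, ensemble and auxiliary terms as configured", {
  b <- list(L1 = 1, L2 = 2, L_ensemble = 0.5, L_EPKT = 0.25, L_fusion_ce = 0.125)
  # bare three-term objective
  expect_equal(global_total(b, T = 4, w_epkt = 0, w_fce = 0), 1 + 2 + 16 * 0.5)
  # defaults add both auxiliary terms at weight 1
  expect_equal(global_total(b, T = 4), 11 + 0.25 + 0.125)
  z <- list(L1 = 0, L2 = 0, L_ensemble = 0, L_EPKT = 0, L_fusion_ce = 0)
  expect_equal(global_total(z), 0)
  expect_error(global_total(list(L1 = 1)), "L2")
})

test_that("tape-side losses equal the numeric reference and detach the teachers", {
  ns <- asNamespace("ofml")
  set.seed(13)
  z1 <- matrix(rnorm(8), 2, 4)
  z2 <- matrix(rnorm(8), 2, 4)
  zfv <- matrix(rnorm(8), 2, 4)
  Y <- matrix(c(1, 0, 0, 0, 0, 0, 1, 0), 2, 4, byrow = TRUE)
  n1 <- ns$ag_param(z1); n2 <- ns$ag_param(z2); nf <- ns$ag_param(zfv)
  lb <- ns$loss_bundle_nodes(n1, n2, nf, Y, T = 4)
  # cross-check every component against the numeric API
  expect_equal(ns$val(lb$parts$L_net1), cross_entropy(soften(z1, 1), c(0, 2)),
               tolerance = 1e-9)
  expect_equal(ns$val(lb$parts$L_FPKT1),
               kl_divergence(soften(z1, 4), soften(zfv, 4)), tolerance = 1e-9)
  expect_equal(ns$val(lb$parts$L1),
               branch_total(z1, c(0, 2), zfv, 4)$L_total, tolerance = 1e-9)
  ze <- ensemble_logits(z1, z2)
  expect_equal(ns$val(lb$parts$L_ensemble),
               cross_entropy(soften(ze, 1), c(0, 2)), tolerance = 1e-9)
  expect_equal(ns$val(lb$parts$L_EPKT),
               kl_divergence(soften(ze, 4), soften(zfv, 4)), tolerance = 1e-9)
  expect_equal(ns$val(lb$total),
               global_total(list(L1 = ns$val(lb$parts$L1),
                                 L2 = ns$val(lb$parts$L2),
                                 L_ensemble = ns$val(lb$parts$L_ensemble),
                                 L_EPKT = ns$val(lb$parts$L_EPKT),
                                 L_fusion_ce = ns$val(lb$parts$L_fusion_ce)),
                            T = 4), tolerance = 1e-9)
  # teacher detachment: backward through L1 alone leaves the fusion logits
  # without gradient (the transfer treats them as a fixed teacher)
  ns$ag_backward(lb$parts$L1)
  expect_null(nf$grad)
  expect_false(is.null(n1$grad))
  ns$zero_grads(list(n1, n2, nf))
  # while the EPKT/fusion-CE terms do train the fusion head
  ns$ag_backward(lb$parts$L_EPKT)
  expect_false(is.null(nf$grad))
  ns$zero_grads(list(n1, n2, nf))
})
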