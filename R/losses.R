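# Online-fusion-mutual-learning losses.
#
# Numeric (tape-free) implementations are the user-facing reference API;
# train() assembles the same quantities on the autodiff tape (see
# loss_bundle_nodes) so that a test can cross-check both routes.
#
# Conventions: logits may be a length-M vector (one sample) or an N x M
# matrix; labels are 0-based class indices or points on the M-simplex
# (soft labels, e.g. from Mixup). Batch losses are means over samples.
# Cross-entropies are standard negative log-likelihoods (non-negative).

EPS_LOG <- 1e-12

as_logit_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, 1L)
}

as_label_matrix <- function(y, M) {
  if (is.matrix(y)) {
    stopifnot(ncol(y) == M)
    return(y)
  }
  if (is.numeric(y) && length(y) == M && !is.null(attr(y, "simplex"))) {
    return(matrix(y, 1L))
  }
  # treat length-M vectors summing to 1 with any non-integer entry as soft
  if (is.numeric(y) && length(y) == M &&
      abs(sum(y) - 1) < 1e-8 && any(y %% 1 != 0)) {
    return(matrix(y, 1L))
  }
  oh <- matrix(0, length(y), M)
  yi <- as.integer(y)
  if (any(yi < 0L | yi >= M)) stop("class index out of range [0, M)")
  oh[cbind(seq_along(yi), yi + 1L)] <- 1
  oh
}

softmax_rows <- function(z) {
  s <- exp(z - apply(z, 1L, max))
  s / rowSums(s)
}

#' Temperature-softened class probabilities
#'
#' Softmax of `logits / T`, numerically stabilized by max-subtraction. As
#' `T` grows the distribution approaches uniform; `T = 1` is the ordinary
#' softmax.
#'
#' @param logits Length-M vector or N x M matrix of logits.
#' @param T Positive temperature.
#' @return Probabilities with the same shape as `logits`; rows sum to 1.
#' @export
soften <- function(logits, T = 1) {
  if (!is.numeric(T) || length(T) != 1L || T <= 0) {
    stop("temperature T must be a positive scalar")
  }
  z <- as_logit_matrix(logits) / T
  p <- softmax_rows(z)
  if (!is.matrix(logits)) p <- drop(p)
  p
}

#' Cross-entropy between predicted probabilities and labels
#'
#' `-sum_m y_m log p_m`, averaged over samples. Hard labels are 0-based class
#' indices (the indicator selects the true-class probability); soft label
#' distributions (e.g. Mixup) are accepted as simplex vectors/rows.
#'
#' @param probs Probabilities on the simplex (vector or N x M matrix),
#'   typically `soften(logits, 1)`.
#' @param y 0-based class index/indices, or simplex label rows.
#' @return Non-negative mean cross-entropy (nats).
#' @export
cross_entropy <- function(probs, y) {
  p <- as_logit_matrix(probs)
  if (any(p < -1e-8) || any(abs(rowSums(p) - 1) > 1e-6)) {
    stop("probs must lie on the probability simplex")
  }
  yy <- as_label_matrix(y, ncol(p))
  if (nrow(yy) != nrow(p)) stop("label/probability row mismatch")
  if (any(yy > 0 & p < EPS_LOG)) {
    # a zero probability at a supported class is clamped to keep the log finite
    warning("true-class probabilities clamped at ", EPS_LOG,
            " in cross_entropy")
  }
  -mean(rowSums(yy * log(pmax(p, EPS_LOG))))
}

#' Kullback-Leibler divergence KL(p || q)
#'
#' `sum_m p_m log(p_m / q_m)` for simplex vectors, or the mean over paired
#' rows of two matrices; `q` is clamped away from zero.
#'
#' @param p,q Simplex vectors or N x M matrices (rows paired).
#' @return Non-negative divergence in nats.
#' @export
kl_divergence <- function(p, q) {
  pm <- as_logit_matrix(p)
  qm <- as_logit_matrix(q)
  if (any(!is.finite(pm)) || any(!is.finite(qm))) {
    stop("kl_divergence: non-finite input")
  }
  if (!all(dim(pm) == dim(qm))) stop("kl_divergence: shape mismatch")
  terms <- pm * (log(pmax(pm, EPS_LOG)) - log(pmax(qm, EPS_LOG)))
  mean(rowSums(terms))
}

#' Per-branch mutual-learning loss
#'
#' A backbone's total loss couples its supervised cross-entropy with a
#' fusion-to-branch knowledge-transfer term:
#' `L_net  = CE(soften(branch, 1), y)`,
#' `L_FPKT = KL(soften(branch, T) || soften(fusion, T))` (fusion acts as a
#' fixed teacher: its logits are detached), and
#' `L = L_net + T^2 * L_FPKT`.
#'
#' @param logits_branch Branch logits (vector or N x M matrix).
#' @param y Labels as in [cross_entropy()].
#' @param logits_fusion Fusion-classifier logits, same shape.
#' @param T Distillation temperature (default 4).
#' @return List with `L_net`, `L_FPKT`, `L_total`.
#' @export
branch_total <- function(logits_branch, y, logits_fusion, T = 4) {
  l_net <- cross_entropy(soften(logits_branch, 1), y)
  l_fpkt <- kl_divergence(soften(logits_branch, T), soften(logits_fusion, T))
  list(L_net = l_net, L_FPKT = l_fpkt, L_total = l_net + T^2 * l_fpkt)
}

#' Total training loss
#'
#' `L_f = L1 + L2 + T^2 * L_ensemble + w_epkt * L_EPKT + w_fce * L_fusion_ce`.
#' Setting `w_epkt = w_fce = 0` gives the bare three-term objective
#' (branch totals plus the temperature-scaled ensemble cross-entropy); the
#' defaults add the ensemble-to-fusion transfer term and a supervised
#' cross-entropy on the fusion head so that the fusion classifier is trained.
#'
#' @param bundle Named list with `L1`, `L2`, `L_ensemble` and (if the weights
#'   are nonzero) `L_EPKT`, `L_fusion_ce` — e.g. a row of a training history.
#' @param T Distillation temperature (default 4).
#' @param w_epkt,w_fce Weights of the two auxiliary terms (default 1).
#' @return The scalar total loss.
#' @export
global_total <- function(bundle, T = 4, w_epkt = 1, w_fce = 1) {
  need <- c("L1", "L2", "L_ensemble")
  if (!all(need %in% names(bundle))) {
    stop("bundle must contain L1, L2, L_ensemble")
  }
  tot <- bundle$L1 + bundle$L2 + T^2 * bundle$L_ensemble
  if (w_epkt != 0) tot <- tot + w_epkt * bundle$L_EPKT
  if (w_fce != 0) tot <- tot + w_fce * bundle$L_fusion_ce
  tot
}

# ---- tape-side loss assembly ------------------------------------------------

# cross-entropy node: logits node z, constant soft-label matrix Y
ce_node <- function(z, Y) {
  n <- nrow(Y)
  ag_scale(ag_sum(ag_cmul(ag_log(ag_softmax_rows(z)), -Y)), 1 / n)
}

# KL(soften(student,T) || soften(teacher,T)); teacher is a constant matrix
kl_student_node <- function(z_student, teacher_logits, T) {
  n <- nrow(teacher_logits)
  q <- softmax_rows(teacher_logits / T)
  ps <- ag_softmax_rows(ag_scale(z_student, 1 / T))
  terms <- ag_mul(ps, ag_sub(ag_log(ps), ag_node(log(pmax(q, EPS_LOG)))))
  ag_scale(ag_sum(terms), 1 / n)
}

# KL(p_const || soften(z_teachee, T)); gradient flows into z_teachee only
kl_teachee_node <- function(p_const_logits, z_teachee, T) {
  n <- nrow(p_const_logits)
  p <- softmax_rows(p_const_logits / T)
  const_part <- sum(p * log(pmax(p, EPS_LOG))) / n
  qf <- ag_softmax_rows(ag_scale(z_teachee, 1 / T))
  ag_add(ag_node(const_part),
         ag_scale(ag_sum(ag_cmul(ag_log(qf), -p)), 1 / n))
}

# Assemble every loss term present for the given head flags. Returns
# list(total = scalar node, parts = named list of scalar nodes).
loss_bundle_nodes <- function(z1, z2, zf, Y, T, w_epkt = 1, w_fce = 1) {
  parts <- list()
  branches <- list()
  if (!is.null(z1)) {
    parts$L_net1 <- ce_node(z1, Y)
    branches$z1 <- z1
  }
  if (!is.null(z2)) {
    parts$L_net2 <- ce_node(z2, Y)
    branches$z2 <- z2
  }
  ze <- if (!is.null(z1) && !is.null(z2)) ag_scale(ag_add(z1, z2), 0.5) else NULL
  if (!is.null(zf)) {
    if (!is.null(z1)) parts$L_FPKT1 <- kl_student_node(z1, val(zf), T)
    if (!is.null(z2)) parts$L_FPKT2 <- kl_student_node(z2, val(zf), T)
    if (w_fce != 0) parts$L_fusion_ce <- ce_node(zf, Y)
  }
  if (!is.null(ze)) parts$L_ensemble <- ce_node(ze, Y)
  if (!is.null(ze) && !is.null(zf) && w_epkt != 0) {
    parts$L_EPKT <- kl_teachee_node(val(ze), zf, T)
  }
  total <- NULL
  addt <- function(a, b) if (is.null(a)) b else ag_add(a, b)
  l1 <- parts$L_net1
  if (!is.null(parts$L_FPKT1)) l1 <- ag_add(l1, ag_scale(parts$L_FPKT1, T^2))
  l2 <- parts$L_net2
  if (!is.null(parts$L_FPKT2)) l2 <- ag_add(l2, ag_scale(parts$L_FPKT2, T^2))
  if (!is.null(l1)) { parts$L1 <- l1; total <- addt(total, l1) }
  if (!is.null(l2)) { parts$L2 <- l2; total <- addt(total, l2) }
  if (!is.null(parts$L_ensemble)) {
    total <- addt(total, ag_scale(parts$L_ensemble, T^2))
  }
  if (!is.null(parts$L_EPKT)) total <- addt(total, ag_scale(parts$L_EPKT, w_epkt))
  if (!is.null(parts$L_fusion_ce)) {
    total <- addt(total, ag_scale(parts$L_fusion_ce, w_fce))
  }
  parts$L_f <- total
  list(total = total, parts = parts, ensemble = ze)
}
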