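# Objective terms: inter-/intra-view contrastive losses (InfoNCE-style,
# cosine similarity, temperature tau), the three-class sign cross-entropy,
# the combined losses, and the projection mean-squared-error for genes
# lacking TWAS associations.  Each term has a tape builder (used during
# training, so gradients come for free) and a numeric front-end that simply
# evaluates the tape forward pass.

#' Cosine similarity
#'
#' Inner product over the product of norms; defined as 0 when either
#' vector is zero.
#'
#' @param a,b numeric vectors of equal length.
#' @return a real in \[-1, 1\].
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Ordered view pairs (k, k') with k != k'.
view_pairs <- function(m = 4) {
  p <- expand.grid(k = seq_len(m), k2 = seq_len(m))
  p[p$k != p$k2, , drop = FALSE]
}

# Inter-view loss for one polarity: mean over ordered view pairs and nodes
# of  -log[ exp(sim(z_{i,k}, z_{i,k'})/tau) /
#           sum_{j != i} exp(sim(z_{i,k}, z_{j,k'})/tau) ].
# The denominator excludes j = i, so the term is log-denominator minus
# numerator and may be negative.
inter_one_sign_t <- function(tape, zlist, tau) {
  n <- nrow(zlist[[1]]$value)
  if (n < 2) stopf("inter-view loss needs a batch of at least 2 nodes")
  zn <- lapply(zlist, function(z) ad_row_l2_normalize(tape, z))
  offdiag <- 1 - diag(n)
  logmask <- log(offdiag)
  vp <- view_pairs(length(zlist))
  terms <- vector("list", nrow(vp))
  for (r in seq_len(nrow(vp))) {
    S <- ad_scale(tape, ad_matmul(tape, zn[[vp$k[r]]],
                                  ad_t(tape, zn[[vp$k2[r]]])), 1 / tau)
    m <- row_maxs(S$value + logmask)             # off-diagonal row maxima
    E <- ad_mul_const(tape,
                      ad_exp(tape, ad_sub_const(tape, S, matrix(m, n, n))),
                      offdiag)
    logden <- ad_add_const(tape, ad_log(tape, ad_rowsums(tape, E)),
                           matrix(m, ncol = 1))
    terms[[r]] <- ad_mean(tape, ad_sub(tape, logden, ad_diag(tape, S)))
  }
  ad_scale(tape, Reduce(function(a, b) ad_add(tape, a, b), terms),
           1 / nrow(vp))
}

inter_view_loss_t <- function(tape, z_pos, z_neg, tau) {
  ad_add(tape, inter_one_sign_t(tape, z_pos, tau),
         inter_one_sign_t(tape, z_neg, tau))
}

#' Inter-view contrastive loss
#'
#' For every ordered pair of distinct views and every node, contrasts the
#' node's embedding against the same node (numerator) versus all other
#' nodes (denominator, which excludes the node itself) in the partner view,
#' separately for the positive-graph and negative-graph embeddings; the two
#' polarity losses are summed.  Similarity is cosine at temperature `tau`.
#'
#' @param z_pos,z_neg lists of four nodes x d embedding matrices.
#' @param tau temperature (> 0).
#' @return scalar loss (may be negative).
#' @export
inter_view_loss <- function(z_pos, z_neg, tau = 0.05) {
  stopifnot(tau > 0)
  tape <- ad_tape()
  zp <- lapply(z_pos, function(m) ad_const(tape, m))
  zn <- lapply(z_neg, function(m) ad_const(tape, m))
  as.numeric(inter_view_loss_t(tape, zp, zn, tau)$value)
}

# Intra-view loss: per node,
#   -log[ sum_m exp(sim(z_i, z_{i,m}^+)/tau) /
#         sum_m exp(sim(z_i, z_{i,m}^-)/tau) ],  mean over the batch.
intra_view_loss_t <- function(tape, z, z_pos, z_neg, tau) {
  zn <- ad_row_l2_normalize(tape, z)
  lse <- function(zlist) {
    sims <- lapply(zlist, function(zm)
      ad_scale(tape, ad_rowsums(tape,
        ad_mul(tape, zn, ad_row_l2_normalize(tape, zm))), 1 / tau))
    S <- ad_cbind(tape, sims)                     # n x M
    m <- row_maxs(S$value)
    E <- ad_exp(tape, ad_sub_const(tape, S, matrix(m, nrow(S$value), ncol(S$value))))
    ad_add_const(tape, ad_log(tape, ad_rowsums(tape, E)), matrix(m, ncol = 1))
  }
  ad_mean(tape, ad_sub(tape, lse(z_neg), lse(z_pos)))
}

#' Intra-view contrastive loss
#'
#' Pulls each node's fused embedding toward its four positive-view
#' embeddings and away from its four negative-view embeddings:
#' the per-node term is minus the log-ratio of summed exponentiated
#' similarities, averaged over the batch.
#'
#' @param z fused embeddings (nodes x d).
#' @param z_pos,z_neg lists of four per-view embedding matrices.
#' @param tau temperature (> 0).
#' @return scalar loss.
#' @export
intra_view_loss <- function(z, z_pos, z_neg, tau = 0.05) {
  stopifnot(tau > 0, length(z_pos) == 4, length(z_neg) == 4)
  tape <- ad_tape()
  as.numeric(intra_view_loss_t(
    tape, ad_const(tape, z),
    lapply(z_pos, function(m) ad_const(tape, m)),
    lapply(z_neg, function(m) ad_const(tape, m)), tau)$value)
}

#' Combined contrastive loss
#'
#' Affine combination `(1 - alpha) * l_inter + alpha * l_intra`.
#'
#' @param l_inter,l_intra scalar losses.
#' @param alpha weight in \[0, 1\].
#' @return scalar.
#' @export
contrastive_loss <- function(l_inter, l_intra, alpha = 0.8) {
  stopifnot(alpha >= 0, alpha <= 1)
  (1 - alpha) * l_inter + alpha * l_intra
}

#' Total training loss
#'
#' `l_label + beta * l_cl`; `beta = 0` recovers the no-contrastive-learning
#' ablation.
#'
#' @param l_label scalar cross-entropy loss.
#' @param l_cl scalar contrastive loss.
#' @param beta nonnegative weight.
#' @return scalar.
#' @export
total_loss <- function(l_label, l_cl, beta = 0.01) {
  stopifnot(beta >= 0)
  l_label + beta * l_cl
}

# One-hot over classes (down, none, up) from labels in {-1, 0, 1}.
label_onehot <- function(labels) {
  stopifnot(all(labels %in% c(-1, 0, 1)))
  oh <- matrix(0, length(labels), 3,
               dimnames = list(NULL, c("down", "none", "up")))
  oh[cbind(seq_along(labels), labels + 2)] <- 1
  oh
}

#' Multi-class cross-entropy over sign predictions
#'
#' `-(1/N) sum_i sum_c y_ic log(p_ic)`, with probabilities floored at
#' 1e-12 before the logarithm.  Columns of `probs` are in the order
#' (down, none, up); labels use -1 = down, 0 = none, 1 = up.
#'
#' @param probs N x 3 probability matrix (rows sum to 1).
#' @param labels length-N vector in \{-1, 0, 1\}.
#' @return nonnegative scalar.
#' @export
label_loss <- function(probs, labels) {
  probs <- as_mat(probs)
  stopifnot(ncol(probs) == 3, nrow(probs) == length(labels))
  oh <- label_onehot(labels)
  -mean(rowSums(oh * log(pmax(probs, 1e-12))))
}

label_loss_t <- function(tape, probs, onehot) {
  lp <- ad_log(tape, ad_clamp_min(tape, probs, 1e-12))
  ad_scale(tape, ad_sum(tape, ad_mul_const(tape, lp, onehot)),
           -1 / nrow(onehot))
}

# Numerically safe cross-entropy on raw logits (log-softmax): unlike the
# clamp-then-log route, gradients keep flowing even when the softmax
# underflows, which prevents a saturated predictor from freezing training.
label_loss_logits_t <- function(tape, logits, onehot) {
  m <- row_maxs(logits$value)
  sh <- ad_sub_const(tape, logits,
                     matrix(m, nrow(logits$value), ncol(logits$value)))
  lse <- ad_log(tape, ad_rowsums(tape, ad_exp(tape, sh)))
  lp <- ad_sub(tape, sh, ad_rep_cols(tape, lse, ncol(logits$value)))
  ad_scale(tape, ad_sum(tape, ad_mul_const(tape, lp, onehot)),
           -1 / nrow(onehot))
}

# Predictor MLP logits on the tape: concat(z_u, z_v) -> layers -> 3 logits.
predictor_logits_t <- function(tape, zu, zv, P, layers = 2L) {
  x <- ad_cbind(tape, list(zu, zv))
  for (l in seq_len(layers)) {
    x <- ad_add_bias(tape, ad_matmul(tape, x, P[[paste0("pred.W", l)]]),
                     P[[paste0("pred.b", l)]])
    if (l < layers) x <- ad_relu(tape, x)
  }
  x
}

# Probability triples (columns down, none, up) from the predictor.
predictor_t <- function(tape, zu, zv, P, layers = 2L,
                        normalization = c("softmax", "sigmoid")) {
  normalization <- match.arg(normalization)
  x <- predictor_logits_t(tape, zu, zv, P, layers)
  if (normalization == "softmax") {
    ad_softmax_rows(tape, x)
  } else {
    s <- ad_sigmoid(tape, x)
    ad_div(tape, s, ad_rep_cols(tape, ad_rowsums(tape, s), 3L))
  }
}

#' Predict sign probabilities for node embedding pairs
#'
#' Concatenates the gene and phenotype embeddings and applies the predictor
#' perceptron; the three logits are mapped to a probability triple
#' (down, none, up) summing to 1 — by a normalized exponential by default,
#' or by elementwise sigmoid followed by normalization when
#' `output_normalization = "sigmoid"`.
#'
#' @param z_u gene embedding(s): vector or rows of a matrix.
#' @param z_v phenotype embedding(s), same shape as `z_u`.
#' @param params flat named parameter list containing `pred.W*`/`pred.b*`.
#' @param predictor_layers perceptron depth (1..4).
#' @param output_normalization `"softmax"` or `"sigmoid"`.
#' @return matrix with columns `p_down`, `p_none`, `p_up` (one row per pair).
#' @export
predict_sign <- function(z_u, z_v, params, predictor_layers = 2L,
                         output_normalization = c("softmax", "sigmoid")) {
  output_normalization <- match.arg(output_normalization)
  if (!is.matrix(z_u)) z_u <- matrix(z_u, nrow = 1)
  if (!is.matrix(z_v)) z_v <- matrix(z_v, nrow = 1)
  tape <- ad_tape()
  P <- lapply(params, function(v) ad_const(tape, v))
  probs <- predictor_t(tape, ad_const(tape, z_u), ad_const(tape, z_v),
                       P, predictor_layers, output_normalization)$value
  colnames(probs) <- c("p_down", "p_none", "p_up")
  probs
}

# Projection MLP on the tape (two layers, rectifier hidden).
projection_forward_t <- function(tape, X, P) {
  h <- ad_relu(tape, ad_add_bias(tape, ad_matmul(tape, X, P[["pmlp.W1"]]),
                                 P[["pmlp.b1"]]))
  ad_add_bias(tape, ad_matmul(tape, h, P[["pmlp.W2"]]), P[["pmlp.b2"]])
}

init_projection_params <- function(f, d, seed = 1L) {
  h <- max(2L * d, 32L)   # wide hidden layer so the regression can interpolate
  with_seed(seed, list(
    pmlp.W1 = glorot(f, h), pmlp.b1 = matrix(0, 1, h),
    pmlp.W2 = glorot(h, d), pmlp.b2 = matrix(0, 1, d)))
}

#' Projection mean-squared-error
#'
#' Mean squared L2 distance between the projection perceptron's output on
#' the raw feature rows of TWAS genes and their frozen final embeddings:
#' the objective used to bring genes lacking TWAS associations into the
#' trained embedding space.
#'
#' @param h0_rows feature rows (genes x f).
#' @param targets frozen embeddings (genes x d).
#' @param params projection parameter list (`pmlp.*`).
#' @return nonnegative scalar.
#' @export
projection_mse <- function(h0_rows, targets, params) {
  tape <- ad_tape()
  P <- lapply(params, function(v) ad_const(tape, v))
  out <- projection_forward_t(tape, ad_const(tape, as_mat(h0_rows)), P)$value
  mean(rowSums((out - as_mat(targets))^2))
}
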