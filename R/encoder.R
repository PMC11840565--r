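# Sign-aware graph-attention encoder.
#
# Each augmented view is split into a positive-only and a negative-only
# subgraph.  One attention encoder (two single-head layers) is shared by
# the positive subgraphs of all views, another by the negative subgraphs.
# Per view k and polarity zeta, the raw input features and both layer
# outputs are concatenated and mapped by a view-specific projection
# W_k^zeta to the embedding dimension d; a two-layer perceptron fuses the
# eight per-view embeddings of every node into its final representation.

# Directed edge index (both directions of every undirected edge) plus a
# self-loop on every node, over the combined node indexing.
gat_edge_index <- function(graph) {
  n <- graph$n_nodes
  if (n_edges(graph)) {
    gi <- graph$edges$gene
    pj <- phen_node(graph, graph$edges$phenotype)
    src <- c(gi, pj, seq_len(n))
    dst <- c(pj, gi, seq_len(n))
  } else {
    src <- dst <- seq_len(n)
  }
  cbind(src = src, dst = dst)
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

# Encoder parameter-set key.  Under the default "sign" sharing there is one
# encoder per polarity (shared by all four views); under "source_sign" the
# original-graph views (1, 2) and diffusion-graph views (3, 4) get separate
# encoders per polarity (four encoders total).
enc_key <- function(z, k, sharing) {
  if (sharing == "sign") paste0("enc.", z)
  else paste0("enc.", z, ".", if (k <= 2) "orig" else "diff")
}

# Flat named parameter list for the whole model.  `f` is the input feature
# dimension (= node count), `d` the embedding dimension.
init_params <- function(f, d, predictor_layers = 2L, seed = 1L,
                        sharing = c("sign", "source_sign")) {
  sharing <- match.arg(sharing)
  with_seed(seed, {
    p <- list()
    keys <- unique(unlist(lapply(1:4, function(k)
      c(enc_key("pos", k, sharing), enc_key("neg", k, sharing)))))
    for (key in keys) {
      p[[paste0(key, ".W1")]] <- glorot(f, d)
      p[[paste0(key, ".a1s")]] <- glorot(d, 1)
      p[[paste0(key, ".a1d")]] <- glorot(d, 1)
      p[[paste0(key, ".W2")]] <- glorot(d, d)
      p[[paste0(key, ".a2s")]] <- glorot(d, 1)
      p[[paste0(key, ".a2d")]] <- glorot(d, 1)
    }
    for (z in c("pos", "neg"))
      for (k in 1:4)
        p[[paste0("proj.k", k, ".", z)]] <- glorot(f + 2 * d, d)
    p[["fuse.W1"]] <- glorot(8 * d, d)
    p[["fuse.b1"]] <- matrix(0, 1, d)
    p[["fuse.W2"]] <- glorot(d, d)
    p[["fuse.b2"]] <- matrix(0, 1, d)
    dims <- predictor_dims(d, predictor_layers)
    for (l in seq_along(dims$inp)) {
      p[[paste0("pred.W", l)]] <- glorot(dims$inp[l], dims$out[l])
      p[[paste0("pred.b", l)]] <- matrix(0, 1, dims$out[l])
    }
    p
  })
}

predictor_dims <- function(d, layers) {
  layers <- as.integer(layers)
  if (layers < 1L || layers > 4L) stopf("predictor_layers must be in 1..4")
  # hidden width 2d: the score is an interaction of the two embeddings, and
  # rectifier layers need width to express it
  widths <- c(2 * d, rep(2 * d, layers - 1L), 3L)
  list(inp = widths[-length(widths)], out = widths[-1])
}

# One single-head attention layer on the tape.  `ei` is the directed edge
# index with self-loops.  Scores use the standard split attention vector
# (source and destination halves) through a leaky rectifier; weights are
# softmax-normalized over each destination's in-neighbourhood; aggregation
# is followed by an ELU.
gat_layer_t <- function(tape, H, ei, W, a_s, a_d, n, slope = 0.2) {
  Wh <- ad_matmul(tape, H, W)
  ss <- ad_matmul(tape, Wh, a_s)
  sd <- ad_matmul(tape, Wh, a_d)
  s <- ad_add(tape, ad_gather_rows(tape, ss, ei[, 1]),
              ad_gather_rows(tape, sd, ei[, 2]))
  s <- ad_leaky_relu(tape, s, slope)
  # softmax over incoming edges of each destination, max-stabilized
  mfull <- stats::ave(s$value[, 1], ei[, 2], FUN = max)
  e <- ad_exp(tape, ad_sub_const(tape, s, matrix(mfull, ncol = 1)))
  denom <- ad_scatter_rowsum(tape, e, ei[, 2], n)
  alpha <- ad_div(tape, e, ad_gather_rows(tape, denom, ei[, 2]))
  msg <- ad_rowscale(tape, ad_gather_rows(tape, Wh, ei[, 1]), alpha)
  out <- ad_scatter_rowsum(tape, msg, ei[, 2], n)
  list(h = ad_elu(tape, out), alpha = alpha)
}

#' Single graph-attention layer (forward pass)
#'
#' Exposed mainly for inspection and testing: computes one single-head
#' attention layer over a sign-specific subgraph.  Self-loops are added to
#' every node, so isolated nodes return the activated transform of their
#' own features.
#'
#' @param features numeric matrix (nodes x input-dim).
#' @param graph an `sbgraph` supplying the edge structure (signs ignored).
#' @param W transform matrix (input-dim x d).
#' @param a_src,a_dst attention vector halves (d x 1) applied to the
#'   transformed source / destination features.
#' @param slope leaky-rectifier slope for attention scores.
#' @param return_attention if `TRUE`, also return the per-edge attention
#'   weights and the edge index.
#' @return the next layer's features (nodes x d), or a list with `h`,
#'   `alpha`, `edge_index` when `return_attention` is set.
#' @export
attention_layer <- function(features, graph, W, a_src, a_dst,
                            slope = 0.2, return_attention = FALSE) {
  tape <- ad_tape()
  ei <- gat_edge_index(graph)
  res <- gat_layer_t(tape, ad_const(tape, features), ei,
                     ad_const(tape, W), ad_const(tape, a_src),
                     ad_const(tape, a_dst), graph$n_nodes, slope)
  if (return_attention)
    list(h = res$h$value, alpha = as.numeric(res$alpha$value), edge_index = ei)
  else res$h$value
}

# Encode one view (tape): runs the zeta-polarity encoder over the
# zeta-polarity subgraph, concatenates h(0) || h(1) || h(2), projects with
# W_k^zeta.  `P` is the named list of parameter nodes.
encode_view_t <- function(tape, split, H0, P, k, sharing = "sign") {
  n <- nrow(H0$value)
  out <- list()
  for (z in c("pos", "neg")) {
    g <- if (z == "pos") split$positive else split$negative
    key <- enc_key(z, k, sharing)
    ei <- gat_edge_index(g)
    l1 <- gat_layer_t(tape, H0, ei,
                      P[[paste0(key, ".W1")]],
                      P[[paste0(key, ".a1s")]],
                      P[[paste0(key, ".a1d")]], n)
    l2 <- gat_layer_t(tape, l1$h, ei,
                      P[[paste0(key, ".W2")]],
                      P[[paste0(key, ".a2s")]],
                      P[[paste0(key, ".a2d")]], n)
    cat3 <- ad_cbind(tape, list(H0, l1$h, l2$h))
    out[[z]] <- ad_matmul(tape, cat3, P[[paste0("proj.k", k, ".", z)]])
  }
  out
}

#' Encode one augmented view into sign-specific embeddings
#'
#' Runs the positive encoder on the view's positive subgraph and the
#' negative encoder on its negative subgraph (two attention layers each),
#' concatenates the input features with both layer outputs, and applies the
#' view-specific projection to dimension `d`.
#'
#' @param split a [split_by_sign()] result for the view.
#' @param features initial node feature matrix (nodes x f).
#' @param params flat named parameter list (see `init_params`).
#' @param k view index in 1..4 (selects the projection `W_k`).
#' @param sharing `"sign"` (one encoder per polarity, shared by all views;
#'   the default) or `"source_sign"` (separate encoders for original- and
#'   diffusion-graph views).
#' @return list with matrices `pos` and `neg`, each nodes x d.
#' @export
encode_view <- function(split, features, params, k, sharing = "sign") {
  tape <- ad_tape()
  P <- lapply(params, function(v) ad_const(tape, v))
  res <- encode_view_t(tape, split, ad_const(tape, features), P, k, sharing)
  list(pos = res$pos$value, neg = res$neg$value)
}

# Fusion MLP on the tape: concat 4 positive then 4 negative per-view
# embeddings, two-layer perceptron with rectifier hidden layer.
fuse_views_t <- function(tape, z_pos, z_neg, P) {
  x <- ad_cbind(tape, c(z_pos, z_neg))
  h <- ad_relu(tape, ad_add_bias(tape, ad_matmul(tape, x, P[["fuse.W1"]]),
                                 P[["fuse.b1"]]))
  ad_add_bias(tape, ad_matmul(tape, h, P[["fuse.W2"]]), P[["fuse.b2"]])
}

#' Fuse per-view embeddings into final node representations
#'
#' Concatenates the four positive-view then four negative-view embeddings
#' of every node (8d columns) and applies a two-layer perceptron (hidden
#' width d, rectifier) to produce the final d-dimensional embedding.
#'
#' @param z_pos,z_neg lists of four nodes x d matrices (view order 1..4).
#' @param params flat named parameter list.
#' @return nodes x d matrix of fused embeddings.
#' @export
fuse_views <- function(z_pos, z_neg, params) {
  if (length(z_pos) != 4 || length(z_neg) != 4)
    stopf("fuse_views needs exactly 4 positive and 4 negative view embeddings")
  tape <- ad_tape()
  P <- lapply(params, function(v) ad_const(tape, v))
  zp <- lapply(z_pos, function(m) ad_const(tape, m))
  zn <- lapply(z_neg, function(m) ad_const(tape, m))
  fuse_views_t(tape, zp, zn, P)$value
}

# Full encoder forward on one tape: 4 views -> 8 per-view embeddings ->
# fused z.  `splits` is a list of 4 split_by_sign() results.
model_forward_t <- function(tape, splits, H0, P, sharing = "sign") {
  z_pos <- vector("list", 4)
  z_neg <- vector("list", 4)
  for (k in 1:4) {
    zz <- encode_view_t(tape, splits[[k]], H0, P, k, sharing)
    z_pos[[k]] <- zz$pos
    z_neg[[k]] <- zz$neg
  }
  list(z_pos = z_pos, z_neg = z_neg,
       z = fuse_views_t(tape, z_pos, z_neg, P))
}
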