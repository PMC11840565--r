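# Initial node features: gene rows come from the sequence-similarity matrix,
# phenotype rows are one-hot indicators (the model defines gene features
# only, so phenotypes get a stable, parameter-free encoding).

#' Build the initial node feature matrix
#'
#' Stacks an \eqn{\mathcal{N} \times \mathcal{N}} feature matrix over the
#' combined node ordering: the gene block equals the gene similarity matrix
#' padded with zeros over the phenotype columns (row `i` is the initial
#' feature \eqn{h_i^{(0)}} of gene `i`); the phenotype block holds one-hot
#' indicator rows over the phenotype columns.
#'
#' @param sim a [gene_similarity()] whose `gene_order` must match
#'   `graph$gene_ids` exactly.
#' @param graph an `sbgraph`.
#' @return numeric matrix of dimension `n_nodes x n_nodes` with node
#'   identifiers as dimnames.
#' @export
build_feature_matrix <- function(sim, graph) {
  stopifnot(inherits(sim, "gene_similarity"), inherits(graph, "sbgraph"))
  if (!identical(sim$gene_order, graph$gene_ids)) {
    bad <- which(sim$gene_order != graph$gene_ids)[1]
    if (is.na(bad)) bad <- min(length(sim$gene_order), length(graph$gene_ids)) + 1L
    stopf("similarity gene order does not match graph gene order (first mismatch at position %d: %s vs %s)",
          bad,
          if (bad <= length(sim$gene_order)) sim$gene_order[bad] else "<absent>",
          if (bad <= length(graph$gene_ids)) graph$gene_ids[bad] else "<absent>")
  }
  ng <- n_genes(graph)
  np <- n_phenotypes(graph)
  n <- ng + np
  X <- matrix(0, n, n)
  if (ng) X[seq_len(ng), seq_len(ng)] <- sim$matrix
  if (np) X[cbind(ng + seq_len(np), ng + seq_len(np))] <- 1
  ids <- c(graph$gene_ids, graph$phenotype_ids)
  dimnames(X) <- list(ids, ids)
  X
}
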