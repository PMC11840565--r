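# Signed bipartite graph data model: genes on one side, phenotypes on the
# other, every edge labelled +1 (up-regulation) or -1 (down-regulation).

#' Construct a signed bipartite gene-phenotype graph
#'
#' The central container of the package: two disjoint node sets (genes and
#' phenotypes) and signed edges between them.  Edges are stored by integer
#' index into `gene_ids` / `phenotype_ids`; the sign of an edge encodes the
#' direction of regulation inferred from, e.g., the sign of a TWAS z-score.
#' Pairs with no stored edge are "undefined" (class 0) and are never kept as
#' edges.
#'
#' @param gene_ids character vector of gene identifiers (ordered; defines
#'   gene node indices).
#' @param phenotype_ids character vector of phenotype identifiers.
#' @param edges data frame with columns `gene`, `phenotype` (either character
#'   identifiers or integer indices) and `sign` (must be exactly +1 or -1).
#' @return an object of class `"sbgraph"` with elements `gene_ids`,
#'   `phenotype_ids`, `edges` (integer-indexed data frame) and `n_nodes`.
#' @examples
#' g <- signed_bipartite_graph(c("g1", "g2"), "p1",
#'   data.frame(gene = c("g1", "g2"), phenotype = "p1", sign = c(1, -1)))
#' g$n_nodes
#' @export
signed_bipartite_graph <- function(gene_ids, phenotype_ids,
                                   edges = data.frame(gene = integer(),
                                                      phenotype = integer(),
                                                      sign = integer())) {
  gene_ids <- as.character(gene_ids)
  phenotype_ids <- as.character(phenotype_ids)
  if (anyDuplicated(gene_ids)) stopf("duplicate gene identifiers")
  if (anyDuplicated(phenotype_ids)) stopf("duplicate phenotype identifiers")
  if (length(intersect(gene_ids, phenotype_ids)))
    stopf("gene and phenotype identifier sets overlap")
  edges <- as.data.frame(edges)
  if (!all(c("gene", "phenotype", "sign") %in% names(edges)))
    stopf("edges must have columns gene, phenotype, sign")
  gi <- if (is.numeric(edges$gene)) as.integer(edges$gene)
        else match(as.character(edges$gene), gene_ids)
  pi <- if (is.numeric(edges$phenotype)) as.integer(edges$phenotype)
        else match(as.character(edges$phenotype), phenotype_ids)
  if (anyNA(gi) || any(gi < 1L) || any(gi > length(gene_ids)))
    stopf("edge references unknown gene")
  if (anyNA(pi) || any(pi < 1L) || any(pi > length(phenotype_ids)))
    stopf("edge references unknown phenotype")
  sg <- as.integer(edges$sign)
  if (length(sg) && !all(sg %in% c(-1L, 1L)))
    stopf("edge signs must be exactly +1 or -1")
  key <- (gi - 1) * max(1L, length(phenotype_ids)) + pi
  if (anyDuplicated(key))
    stopf("duplicate (gene, phenotype) pair in edge set")
  structure(list(
    gene_ids = gene_ids,
    phenotype_ids = phenotype_ids,
    edges = data.frame(gene = gi, phenotype = pi, sign = sg),
    n_nodes = length(gene_ids) + length(phenotype_ids)
  ), class = "sbgraph")
}

n_genes <- function(g) length(g$gene_ids)
n_phenotypes <- function(g) length(g$phenotype_ids)

#' Number of edges of a signed bipartite graph
#' @param graph an `sbgraph`.
#' @return integer edge count.
#' @export
n_edges <- function(graph) nrow(graph$edges)

# Node index of phenotype p in the combined (genes first) indexing.
phen_node <- function(g, p) n_genes(g) + p

# Replace the edge table, keeping node sets.
set_edges <- function(g, edges) {
  g$edges <- edges
  rownames(g$edges) <- NULL
  g
}

# Linearized (gene, phenotype) keys for fast pair membership tests.
edge_keys <- function(g, gene = g$edges$gene, phenotype = g$edges$phenotype) {
  (as.numeric(gene) - 1) * n_phenotypes(g) + as.numeric(phenotype)
}

#' @export
print.sbgraph <- function(x, ...) {
  cat(sprintf(
    "Signed bipartite graph: %d genes, %d phenotypes, %d edges (%d +, %d -)\n",
    n_genes(x), n_phenotypes(x), n_edges(x),
    sum(x$edges$sign == 1L), sum(x$edges$sign == -1L)))
  invisible(x)
}

#' Signed adjacency matrix of a bipartite graph
#'
#' Builds the symmetric \eqn{\mathcal{N} \times \mathcal{N}} signed adjacency
#' matrix A over the combined node ordering (genes first, phenotypes after):
#' `A[g, |V|+p] = A[|V|+p, g] = sign` for every edge, zero elsewhere.
#' Gene-gene and phenotype-phenotype blocks are identically zero.
#'
#' @param graph an `sbgraph`.
#' @return numeric matrix with node identifiers as dimnames.
#' @export
adjacency <- function(graph) {
  n <- graph$n_nodes
  A <- matrix(0, n, n)
  ids <- c(graph$gene_ids, graph$phenotype_ids)
  dimnames(A) <- list(ids, ids)
  if (n_edges(graph)) {
    gi <- graph$edges$gene
    pj <- phen_node(graph, graph$edges$phenotype)
    A[cbind(gi, pj)] <- graph$edges$sign
    A[cbind(pj, gi)] <- graph$edges$sign
  }
  A
}

#' Split a graph into positive-only and negative-only subgraphs
#'
#' Each encoder perspective consumes only one edge polarity, so every view is
#' partitioned into a positive graph and a negative graph over the same node
#' sets.
#'
#' @param view an `sbgraph`.
#' @return list with elements `positive` and `negative`, both `sbgraph`s.
#' @export
split_by_sign <- function(view) {
  stopifnot(inherits(view, "sbgraph"))
  list(
    positive = set_edges(view, view$edges[view$edges$sign == 1L, , drop = FALSE]),
    negative = set_edges(view, view$edges[view$edges$sign == -1L, , drop = FALSE])
  )
}
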