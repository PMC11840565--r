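# Synthetic signed bipartite graphs with planted latent-factor structure.
#
# Genes and phenotypes get standard-normal latent factors; the true sign of
# a pair is the sign of their inner product, observed signs are flipped
# independently with a small probability, and the gene similarity matrix is
# a clamped, noisy transform of the cosine between gene factors.  This
# mirrors the empirical observation that genes with similar sequences tend
# to share association signs, so the similarity features are genuinely
# informative about edge signs.

#' Generate a synthetic gene-phenotype association dataset
#'
#' @param n_genes,n_phenotypes node counts.
#' @param n_edges number of observed signed edges (distinct pairs; must not
#'   exceed `n_genes * n_phenotypes`).
#' @param latent_dim latent factor dimension (default 4).
#' @param flip_noise probability that an observed edge sign differs from
#'   the true sign, in \[0, 0.5).
#' @param sim_noise scale of the centered noise added to the similarity
#'   matrix (default 0.05).
#' @param seed integer seed.
#' @param degree_skew if `TRUE`, phenotype degrees follow a power law
#'   (mirroring real TWAS panels where one trait may carry most edges)
#'   instead of the uniform default.
#' @return list of class `"gp_simulation"`: `graph` (an `sbgraph`),
#'   `similarity` (a [gene_similarity()]), and `truth` (list with
#'   `gene_factors`, `phenotype_factors`, `true_sign` matrix).
#' @export
simulate_gp_graph <- function(n_genes, n_phenotypes, n_edges,
                              latent_dim = 4L, flip_noise = 0.1,
                              sim_noise = 0.05, seed = 1L,
                              degree_skew = FALSE) {
  stopifnot(n_genes >= 1, n_phenotypes >= 1,
            n_edges >= 1, n_edges <= as.numeric(n_genes) * n_phenotypes,
            flip_noise >= 0, flip_noise < 0.5, sim_noise >= 0)
  with_seed(seed, {
    U <- matrix(stats::rnorm(n_genes * latent_dim), n_genes, latent_dim)
    V <- matrix(stats::rnorm(n_phenotypes * latent_dim), n_phenotypes,
                latent_dim)
    inner <- U %*% t(V)

    total <- as.numeric(n_genes) * n_phenotypes
    w <- if (degree_skew) {
      pw <- (seq_len(n_phenotypes))^(-1.5)
      rep(pw / sum(pw), times = n_genes)
    } else NULL
    keys <- sample(total, n_edges, prob = w)
    # measure-zero guard: resample pairs whose inner product is exactly 0
    repeat {
      gi <- as.integer((keys - 1) %/% n_phenotypes) + 1L
      pj <- as.integer((keys - 1) %% n_phenotypes) + 1L
      bad <- inner[cbind(gi, pj)] == 0
      if (!any(bad)) break
      repl <- sample(setdiff(seq_len(total), keys), sum(bad))
      keys[bad] <- repl
    }
    true_sign <- sign(inner[cbind(gi, pj)])
    flip <- stats::runif(n_edges) < flip_noise
    obs_sign <- as.integer(ifelse(flip, -true_sign, true_sign))

    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    phen_ids <- sprintf("p%02d", seq_len(n_phenotypes))
    graph <- signed_bipartite_graph(
      gene_ids, phen_ids,
      data.frame(gene = gi, phenotype = pj, sign = obs_sign))

    nrm <- sqrt(rowSums(U^2))
    C <- (U / nrm) %*% t(U / nrm)               # cosine between gene factors
    S <- (1 + C) / 2
    if (sim_noise > 0) {
      E <- matrix(stats::rnorm(n_genes^2, sd = sim_noise), n_genes, n_genes)
      S <- S + (E + t(E)) / 2
    }
    S <- clamp01((S + t(S)) / 2)
    diag(S) <- 1
    similarity <- gene_similarity(S, gene_ids)

    structure(list(graph = graph, similarity = similarity,
                   truth = list(gene_factors = U, phenotype_factors = V,
                                true_sign = sign(inner))),
              class = "gp_simulation")
  })
}

#' @export
print.gp_simulation <- function(x, ...) {
  cat("Synthetic gene-phenotype dataset\n")
  print(x$graph)
  invisible(x)
}

#' AUC of scores against the planted true signs
#'
#' Recovery metric for synthetic data: ranks the given per-pair scores
#' against the latent-factor true signs (not the possibly flipped observed
#' signs).
#'
#' @param truth the `truth` element of a [simulate_gp_graph()] result.
#' @param scores numeric vector of per-pair scores (higher = more "up").
#' @param pairs data frame of integer `gene`, `phenotype` indices.
#' @return AUC in \[0, 1\].
#' @export
truth_auc <- function(truth, scores, pairs) {
  ts <- truth$true_sign[cbind(as.integer(pairs$gene),
                              as.integer(pairs$phenotype))]
  rank_auc(scores, ts > 0)
}

#' Inner-product oracle scores for pairs
#'
#' The task-solvability control: scores a pair by the inner product of its
#' latent factors, the Bayes-optimal statistic under the generative model.
#'
#' @param truth the `truth` element of a [simulate_gp_graph()] result.
#' @param pairs data frame of integer `gene`, `phenotype` indices.
#' @return numeric scores.
#' @export
oracle_scores <- function(truth, pairs) {
  inner <- truth$gene_factors %*% t(truth$phenotype_factors)
  inner[cbind(as.integer(pairs$gene), as.integer(pairs$phenotype))]
}
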