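# Signed Random Walk with Restart (SRWR) diffusion.
#
# A signed surfer starts at a seed node with sign +, keeps its sign on
# positive edges and flips on negative edges.  Balance attenuation factors
# relax strict balance theory: a negative surfer on a negative edge turns
# positive with probability beta, and on a positive edge stays negative with
# probability gamma.  The stationary positive/negative visiting
# probabilities r+ / r- of all seeds are aggregated and symmetrized into the
# signed diffusion matrix r_d, from which a densified "diffusion graph" is
# sparsified back out.

#' Configuration for signed random walk with restart
#'
#' @param c restart probability in (0, 1].
#' @param beta balance attenuation: probability that a negative surfer
#'   turns positive on a negative edge, in \[0, 1\].
#' @param gamma balance attenuation: probability that a negative surfer
#'   stays negative on a positive edge, in \[0, 1\].
#' @param epsilon convergence tolerance on the L1 change of the stacked
#'   (r+, r-) iterate; must be positive.
#' @param max_iter iteration cap.
#' @return object of class `"diffusion_config"`.
#' @export
diffusion_config <- function(c = 0.15, beta = 0.5, gamma = 0.5,
                             epsilon = 1e-9, max_iter = 200L) {
  if (!is.numeric(c) || length(c) != 1 || c <= 0 || c > 1)
    stopf("restart probability c must lie in (0, 1]")
  if (beta < 0 || beta > 1) stopf("beta must lie in [0, 1]")
  if (gamma < 0 || gamma > 1) stopf("gamma must lie in [0, 1]")
  if (epsilon <= 0) stopf("epsilon must be positive")
  if (max_iter < 1) stopf("max_iter must be a positive integer")
  structure(list(c = c, beta = beta, gamma = gamma,
                 epsilon = epsilon, max_iter = as.integer(max_iter)),
            class = "diffusion_config")
}

#' Semi-row normalization of a signed adjacency matrix
#'
#' With \eqn{D_{ii} = \sum_j |A|_{ij}}, the semi-row normalized matrix is
#' \eqn{\tilde A = D^{-1} A}, split into nonnegative parts
#' \eqn{\tilde A_+ = \max(\tilde A, 0)} and
#' \eqn{\tilde A_- = \max(-\tilde A, 0)}.  Zero-degree rows stay all-zero.
#'
#' @param A square signed matrix.
#' @return list of class `"normalized_adjacency"` with `a_plus`, `a_minus`
#'   and `degree`.
#' @export
semi_row_normalize <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stopf("adjacency matrix must be square")
  d <- rowSums(abs(A))
  scale <- ifelse(d > 0, 1 / d, 0)
  At <- A * scale
  structure(list(a_plus = pmax(At, 0), a_minus = pmax(-At, 0), degree = d),
            class = "normalized_adjacency")
}

# Shared iteration matrices: the two coupled updates read, with
# P = t(a_plus), M = t(a_minus),
#   r+ <- (1-c) (P r+ + beta M r- + (1-gamma) P r-) + c q
#   r- <- (1-c) (M r+ + gamma P r- + (1-beta) M r-)
srwr_mats <- function(norm, cfg) {
  P <- t(norm$a_plus)
  M <- t(norm$a_minus)
  list(P = P, M = M,
       Wpp = (1 - cfg$c) * P,
       Wpm = (1 - cfg$c) * (cfg$beta * M + (1 - cfg$gamma) * P),
       Wmp = (1 - cfg$c) * M,
       Wmm = (1 - cfg$c) * (cfg$gamma * P + (1 - cfg$beta) * M))
}

#' Iterative SRWR from one seed node
#'
#' Runs the coupled power iteration for the balance-attenuated signed
#' surfer, starting from `r+ = q` (one-hot at the seed) and `r- = 0`, with
#' simultaneous (Jacobi-style) updates of both vectors, until the L1 change
#' of the stacked iterate drops below `cfg$epsilon` or `cfg$max_iter` is
#' reached.
#'
#' @param norm a [semi_row_normalize()] result.
#' @param seed seed node index.
#' @param cfg a [diffusion_config()].
#' @return list of class `"srwr_result"`: `r_plus`, `r_minus`,
#'   `iterations`, `final_delta`, `converged`.
#' @export
srwr_seed <- function(norm, seed, cfg = diffusion_config()) {
  n <- nrow(norm$a_plus)
  if (seed < 1 || seed > n) stopf("seed index out of range")
  W <- srwr_mats(norm, cfg)
  q <- numeric(n); q[seed] <- 1
  rp <- q; rm <- numeric(n)
  it <- 0L; delta <- Inf
  while (it < cfg$max_iter) {
    it <- it + 1L
    rp2 <- W$Wpp %*% rp + W$Wpm %*% rm + cfg$c * q
    rm2 <- W$Wmp %*% rp + W$Wmm %*% rm
    delta <- sum(abs(rp2 - rp)) + sum(abs(rm2 - rm))
    rp <- rp2; rm <- rm2
    if (delta < cfg$epsilon) break
  }
  conv <- delta < cfg$epsilon
  if (!conv)
    warnf("SRWR did not converge in %d iterations (delta = %.3g)", it, delta)
  structure(list(r_plus = as.numeric(rp), r_minus = as.numeric(rm),
                 iterations = it, final_delta = as.numeric(delta),
                 converged = conv),
            class = "srwr_result")
}

#' Exact SRWR fixed point by dense linear solve
#'
#' Solves the stacked 2N-dimensional linear fixed-point system of the
#' balance-attenuated diffusion directly by dense factorization.  Serves as
#' the independent oracle for [srwr_seed()] on small graphs.
#'
#' @inheritParams srwr_seed
#' @return an `"srwr_result"` (with `iterations = 0`).
#' @export
srwr_exact <- function(norm, seed, cfg = diffusion_config()) {
  n <- nrow(norm$a_plus)
  if (n > 2000) stopf("dense SRWR solve is guarded to N <= 2000 nodes")
  if (seed < 1 || seed > n) stopf("seed index out of range")
  W <- srwr_mats(norm, cfg)
  S <- rbind(cbind(W$Wpp, W$Wpm), cbind(W$Wmp, W$Wmm))
  b <- numeric(2 * n); b[seed] <- cfg$c
  x <- tryCatch(solve(diag(2 * n) - S, b),
                error = function(e)
                  stopf("SRWR fixed-point system is singular; use a restart probability c > 0 (%s)",
                        conditionMessage(e)))
  x <- unname(x)
  structure(list(r_plus = x[seq_len(n)], r_minus = x[n + seq_len(n)],
                 iterations = 0L, final_delta = 0, converged = TRUE),
            class = "srwr_result")
}

#' SRWR diffusion from every seed
#'
#' Stacks the per-seed stationary vectors into score matrices: row `s` of
#' `r_p` (resp. `r_n`) is the positive (negative) visiting-probability
#' vector of seed `s`.  All seeds iterate simultaneously as one dense
#' matrix recurrence.
#'
#' @param norm a [semi_row_normalize()] result.
#' @param cfg a [diffusion_config()].
#' @param seeds integer node subset (default: all nodes).
#' @return list of class `"diffusion_matrix"` with `r_p`, `r_n`, `r_d`
#'   (`NULL` until [symmetrize_diffusion()]), `iterations`, `converged`.
#' @export
srwr_all_seeds <- function(norm, cfg = diffusion_config(),
                           seeds = seq_len(nrow(norm$a_plus))) {
  n <- nrow(norm$a_plus)
  seeds <- as.integer(seeds)
  if (any(seeds < 1L) || any(seeds > n)) stopf("seed index out of range")
  W <- srwr_mats(norm, cfg)
  Q <- matrix(0, n, length(seeds))
  Q[cbind(seeds, seq_along(seeds))] <- 1
  Rp <- Q; Rm <- matrix(0, n, length(seeds))
  it <- 0L; delta <- Inf
  while (it < cfg$max_iter) {
    it <- it + 1L
    Rp2 <- W$Wpp %*% Rp + W$Wpm %*% Rm + cfg$c * Q
    Rm2 <- W$Wmp %*% Rp + W$Wmm %*% Rm
    # worst-case per-seed L1 change, matching the per-seed stopping rule
    delta <- max(colSums(abs(Rp2 - Rp)) + colSums(abs(Rm2 - Rm)))
    Rp <- Rp2; Rm <- Rm2
    if (delta < cfg$epsilon) break
  }
  conv <- delta < cfg$epsilon
  if (!conv)
    warnf("SRWR (all seeds) did not converge in %d iterations (delta = %.3g)",
          it, delta)
  r_p <- matrix(0, n, n); r_n <- matrix(0, n, n)
  r_p[seeds, ] <- t(Rp)
  r_n[seeds, ] <- t(Rm)
  structure(list(r_p = r_p, r_n = r_n, r_d = NULL,
                 iterations = it, converged = conv),
            class = "diffusion_matrix")
}

#' Symmetrize per-seed SRWR scores into the signed diffusion matrix
#'
#' Because visiting probabilities are direction-dependent, the signed
#' diffusion matrix takes the elementwise maxima
#' \eqn{r_d = \max(r_p, r_p^T) - \max(r_n, r_n^T)}, which is exactly
#' symmetric.
#'
#' @param dm a [srwr_all_seeds()] result.
#' @return `dm` with `r_d` filled.
#' @export
symmetrize_diffusion <- function(dm) {
  stopifnot(inherits(dm, "diffusion_matrix"))
  dm$r_d <- pmax(dm$r_p, t(dm$r_p)) - pmax(dm$r_n, t(dm$r_n))
  dm
}

#' Sparsify the diffusion matrix into a signed bipartite graph
#'
#' Restricts `r_d` to the gene-by-phenotype block and keeps the `k_edges`
#' entries of largest magnitude (ties broken by ascending gene then
#' phenotype index); each kept entry becomes an edge with the sign of its
#' diffusion score.  Zero entries are never selected.
#'
#' @param dm a symmetrized `"diffusion_matrix"`.
#' @param template `sbgraph` fixing the node indexing (and identifier sets).
#' @param k_edges number of edges to keep (default: the template's edge
#'   count, preserving density); must be >= 1.
#' @return an `sbgraph` over the template's node sets.
#' @export
diffusion_to_graph <- function(dm, template, k_edges = n_edges(template)) {
  stopifnot(inherits(dm, "diffusion_matrix"), inherits(template, "sbgraph"))
  if (is.null(dm$r_d)) stopf("diffusion matrix not symmetrized; call symmetrize_diffusion()")
  if (k_edges < 1) stopf("k_edges must be >= 1")
  ng <- n_genes(template)
  np <- n_phenotypes(template)
  if (nrow(dm$r_d) != ng + np)
    stopf("diffusion matrix dimension does not match template node count")
  block <- dm$r_d[seq_len(ng), ng + seq_len(np), drop = FALSE]
  idx <- which(block != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warnf("diffusion matrix has no nonzero gene-phenotype entries; empty graph returned")
    return(set_edges(template, template$edges[0, , drop = FALSE]))
  }
  vals <- block[idx]
  ord <- order(-abs(vals), idx[, 1], idx[, 2])
  if (k_edges > nrow(idx)) {
    warnf("k_edges = %d exceeds the %d nonzero entries; returning all of them",
          k_edges, nrow(idx))
    k_edges <- nrow(idx)
  }
  keep <- ord[seq_len(k_edges)]
  set_edges(template, data.frame(gene = as.integer(idx[keep, 1]),
                                 phenotype = as.integer(idx[keep, 2]),
                                 sign = as.integer(sign(vals[keep]))))
}

#' One-call diffusion graph from a signed bipartite graph
#'
#' Convenience wrapper chaining [adjacency()], [semi_row_normalize()],
#' [srwr_all_seeds()], [symmetrize_diffusion()] and [diffusion_to_graph()].
#'
#' @param graph an `sbgraph`.
#' @param cfg a [diffusion_config()].
#' @param k_edges edges kept in the sparsified diffusion graph.
#' @return list with `graph` (the diffusion `sbgraph`) and `matrix`
#'   (the symmetrized `"diffusion_matrix"`).
#' @export
diffuse_graph <- function(graph, cfg = diffusion_config(),
                          k_edges = n_edges(graph)) {
  norm <- semi_row_normalize(adjacency(graph))
  dm <- symmetrize_diffusion(srwr_all_seeds(norm, cfg))
  list(graph = diffusion_to_graph(dm, graph, k_edges), matrix = dm)
}
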