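# Stochastic graph augmentation: each view is the source graph with a
# seeded Bernoulli edge mask (one uniform draw per edge; draws below the
# mask ratio delete the edge).  Two views come from the original graph and
# two from the diffusion graph, giving M = 4 views per epoch.

#' Randomly mask (delete or sign-flip) edges of a graph
#'
#' Draws one uniform(0,1) value per edge under the given seed and removes
#' every edge whose draw falls below `ratio` (the mask-threshold rule).
#' With `strategy = "sign_flip"` the selected edges have their signs
#' flipped instead of being deleted (the perturbation-style augmentation).
#' Node sets are unchanged.
#'
#' @param graph an `sbgraph`.
#' @param ratio masking ratio in \[0, 1\].
#' @param rng_seed integer seed; fully determines the surviving edge set.
#' @param strategy `"delete"` (default) or `"sign_flip"`.
#' @return an `sbgraph`.
#' @export
mask_edges <- function(graph, ratio, rng_seed,
                       strategy = c("delete", "sign_flip")) {
  strategy <- match.arg(strategy)
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio < 0 || ratio > 1)
    stopf("mask ratio must lie in [0, 1]")
  m <- n_edges(graph)
  if (m == 0) return(graph)
  u <- with_seed(rng_seed, stats::runif(m))
  hit <- u < ratio
  if (strategy == "delete") {
    set_edges(graph, graph$edges[!hit, , drop = FALSE])
  } else {
    e <- graph$edges
    e$sign[hit] <- -e$sign[hit]
    set_edges(graph, e)
  }
}

#' Build the four augmented graph views
#'
#' Views 1 and 2 are independent masks of the original graph; views 3 and 4
#' are independent masks of the diffusion graph.  Four distinct sub-seeds
#' are derived deterministically from `rng_seed`, so the full view set is a
#' pure function of `(original, diffusion, ratio, rng_seed)`.
#'
#' @param original the original `sbgraph`.
#' @param diffusion the diffusion `sbgraph` (same node indexing).
#' @param ratio masking ratio in \[0, 1\].
#' @param rng_seed integer seed.
#' @param strategy forwarded to [mask_edges()].
#' @return list of class `"view_set"`: `views` (list of 4 `sbgraph`s) and
#'   `source_tags`.
#' @export
build_views <- function(original, diffusion, ratio, rng_seed,
                        strategy = c("delete", "sign_flip")) {
  strategy <- match.arg(strategy)
  if (!identical(original$gene_ids, diffusion$gene_ids) ||
      !identical(original$phenotype_ids, diffusion$phenotype_ids))
    stopf("original and diffusion graphs must share node indexing")
  src <- list(original, original, diffusion, diffusion)
  views <- lapply(seq_len(4), function(k)
    mask_edges(src[[k]], ratio, derive_seed(rng_seed, k), strategy))
  structure(list(views = views,
                 source_tags = c("original", "original",
                                 "diffusion", "diffusion")),
            class = "view_set")
}
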