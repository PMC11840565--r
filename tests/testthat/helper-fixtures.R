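# Shared fixtures: small graphs built in code.

toy_graph <- function() {
  # 2 genes, 1 phenotype: (g1,p1,+), (g2,p1,-)
  signed_bipartite_graph(
    c("g1", "g2"), "p1",
    data.frame(gene = c("g1", "g2"), phenotype = "p1", sign = c(1L, -1L)))
}

# Random signed bipartite graph with at least one edge.
random_graph <- function(n_genes, n_phenotypes, n_edges, seed) {
  set.seed(seed)
  total <- n_genes * n_phenotypes
  n_edges <- min(n_edges, total)
  keys <- sample(total, n_edges)
  data.frame(
    gene = (keys - 1) %/% n_phenotypes + 1L,
    phenotype = (keys - 1) %% n_phenotypes + 1L,
    sign = sample(c(-1L, 1L), n_edges, replace = TRUE)) |>
    (\(e) signed_bipartite_graph(paste0("g", seq_len(n_genes)),
                                 paste0("p", seq_len(n_phenotypes)), e))()
}

write_tsv_lines <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}

# Small trained model on a synthetic fixture, cached across tests.
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_gp_graph(30, 4, 60, latent_dim = 3, flip_noise = 0,
                               seed = 42)
      sp <- split_edges(sim$graph, 0.8, 1)
      fit <- suppressWarnings(
        gpsign(sp$train, sim$similarity, d = 8, epochs = 15, lr = 5e-3,
               exclude_pairs = sp$test, seed = 1))
      cache <<- list(sim = sim, split = sp, fit = fit)
    }
    cache
  }
})
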