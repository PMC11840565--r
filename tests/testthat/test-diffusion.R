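# SRWR diffusion: normalization, iterative vs exact solver, conservation,
# symmetrization, sparsification.

test_that("semi-row normalization splits signs and preserves row mass", {
  g <- signed_bipartite_graph(c("g1", "g2"), "p1", data.frame(
    gene = c("g1", "g2"), phenotype = "p1", sign = c(1L, -1L)))
  norm <- semi_row_normalize(adjacency(g))
  expect_equal(unname(norm$a_plus[3, ]), c(0.5, 0, 0))
  expect_equal(unname(norm$a_minus[3, ]), c(0, 0.5, 0))

  # all-positive graph: negative part vanishes
  gp <- random_graph(5, 3, 8, 1)
  gp$edges$sign <- 1L
  np <- semi_row_normalize(adjacency(gp))
  expect_true(all(np$a_minus == 0))

  # rows of a_plus + a_minus sum to 1 where degree >= 1, else 0
  for (seed in 1:10) {
    g <- random_graph(6, 4, 9, seed)
    norm <- semi_row_normalize(adjacency(g))
    rs <- rowSums(norm$a_plus + norm$a_minus)
    expect_equal(rs, ifelse(norm$degree > 0, 1, 0), ignore_attr = TRUE)
    # decomposition identity A~ = a_plus - a_minus
    A <- adjacency(g)
    d <- rowSums(abs(A))
    At <- A * ifelse(d > 0, 1 / d, 0)
    expect_lt(max(abs((norm$a_plus - norm$a_minus) - At)), 1e-12)
  }
  expect_error(semi_row_normalize(matrix(0, 2, 3)), "square")
})

test_that("restart probability 1 returns the seed vector immediately", {
  norm <- semi_row_normalize(adjacency(toy_graph()))
  r <- srwr_seed(norm, 2, diffusion_config(c = 1))
  expect_equal(r$r_plus, c(0, 1, 0))
  expect_equal(r$r_minus, rep(0, 3))
  expect_equal(srwr_exact(norm, 2, diffusion_config(c = 1))$r_plus, c(0, 1, 0))
})

test_that("single negative edge fixed point matches the hand-derived solution", {
  # fixed point solved by hand from the coupled updates with c = 0.5,
  # beta = gamma = 0.5: r+ = (26, 1)/45, r- = (4, 14)/45
  g <- signed_bipartite_graph("a", "b",
                              data.frame(gene = "a", phenotype = "b", sign = -1L))
  norm <- semi_row_normalize(adjacency(g))
  cfg <- diffusion_config(c = 0.5, beta = 0.5, gamma = 0.5,
                          epsilon = 1e-13, max_iter = 500)
  ex <- srwr_exact(norm, 1, cfg)
  expect_equal(ex$r_plus, c(26, 1) / 45, tolerance = 1e-12)
  expect_equal(ex$r_minus, c(4, 14) / 45, tolerance = 1e-12)
  it <- srwr_seed(norm, 1, cfg)
  expect_equal(it$r_plus, ex$r_plus, tolerance = 1e-10)
  expect_equal(it$r_minus, ex$r_minus, tolerance = 1e-10)
  expect_true(it$converged)
})

test_that("iterative SRWR agrees with the dense solve across the factor grid", {
  worst <- 0
  for (seed in 1:6) {
    g <- random_graph(7, 5, 14, seed)
    norm <- semi_row_normalize(adjacency(g))
    for (c in c(0.15, 0.5, 0.85)) for (b in c(0, 0.5, 1)) for (ga in c(0, 0.5, 1)) {
      cfg <- diffusion_config(c = c, beta = b, gamma = ga,
                              epsilon = 1e-12, max_iter = 3000)
      seedn <- ((seed * 3) %% nrow(norm$a_plus)) + 1L
      it <- srwr_seed(norm, seedn, cfg)
      ex <- srwr_exact(norm, seedn, cfg)
      l1 <- sum(abs(it$r_plus - ex$r_plus)) + sum(abs(it$r_minus - ex$r_minus))
      worst <- max(worst, l1)
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("probability mass is conserved on graphs without isolated nodes", {
  for (seed in 1:8) {
    g <- random_graph(5, 4, 20, seed)   # dense enough to avoid isolates
    norm <- semi_row_normalize(adjacency(g))
    if (any(norm$degree == 0)) next
    cfg <- diffusion_config(epsilon = 1e-10, max_iter = 1000)
    r <- srwr_seed(norm, 1, cfg)
    expect_equal(sum(r$r_plus) + sum(r$r_minus), 1,
                 tolerance = 10 * cfg$epsilon)
    expect_true(all(r$r_plus >= 0) && all(r$r_minus >= 0))
  }
})

test_that("all-positive graphs reduce to unsigned random walk with restart", {
  for (b in c(0, 0.5, 1)) for (ga in c(0, 0.5, 1)) {
    g <- random_graph(6, 3, 12, 3)
    g$edges$sign <- 1L
    norm <- semi_row_normalize(adjacency(g))
    cfg <- diffusion_config(c = 0.3, beta = b, gamma = ga,
                            epsilon = 1e-12, max_iter = 2000)
    r <- srwr_seed(norm, 2, cfg)
    expect_equal(r$r_minus, rep(0, 9))
    # unsigned RWR: solve (I - (1-c) P^T) r = c q
    P <- t(norm$a_plus)
    q <- numeric(9); q[2] <- 1
    r_rwr <- solve(diag(9) - (1 - cfg$c) * P, cfg$c * q)
    expect_equal(r$r_plus, as.numeric(r_rwr), tolerance = 1e-8)
  }
})

test_that("all-seed diffusion stacks per-seed vectors and conserves mass", {
  g2 <- signed_bipartite_graph("a", "b",
                               data.frame(gene = "a", phenotype = "b", sign = 1L))
  dm <- srwr_all_seeds(semi_row_normalize(adjacency(g2)),
                       diffusion_config(c = 0.5, epsilon = 1e-12,
                                        max_iter = 1000))
  expect_equal(dm$r_p, matrix(c(2, 1, 1, 2) / 3, 2, 2), tolerance = 1e-10)

  # edgeless graph: no transitions, each row is c times its own one-hot
  # (restart mass only; the rest leaks through the zero-degree convention)
  g0 <- signed_bipartite_graph(c("g1", "g2"), "p1")
  cfg0 <- diffusion_config()
  dm0 <- srwr_all_seeds(semi_row_normalize(adjacency(g0)), cfg0)
  expect_equal(dm0$r_p, cfg0$c * diag(3))

  # conservation per row on a connected graph
  g <- random_graph(5, 4, 20, 2)
  norm <- semi_row_normalize(adjacency(g))
  if (all(norm$degree > 0)) {
    cfg <- diffusion_config(epsilon = 1e-10, max_iter = 1000)
    dm <- srwr_all_seeds(norm, cfg)
    expect_equal(rowSums(dm$r_p) + rowSums(dm$r_n), rep(1, 9),
                 tolerance = 10 * cfg$epsilon)
  }

  # per-seed rows match single-seed runs
  r1 <- srwr_seed(norm, 4, diffusion_config(epsilon = 1e-10, max_iter = 1000))
  dm <- srwr_all_seeds(norm, diffusion_config(epsilon = 1e-10, max_iter = 1000),
                       seeds = 4L)
  expect_equal(dm$r_p[4, ], r1$r_plus, tolerance = 1e-12)
  expect_equal(dm$r_n[4, ], r1$r_minus, tolerance = 1e-12)
})

test_that("symmetrization takes elementwise maxima and is exactly symmetric", {
  dm <- structure(list(r_p = matrix(c(0, 0.3, 0.5, 0), 2, 2, byrow = TRUE),
                       r_n = matrix(c(0, 0.2, 0.1, 0), 2, 2, byrow = TRUE),
                       r_d = NULL),
                  class = "diffusion_matrix")
  dm <- symmetrize_diffusion(dm)
  expect_equal(dm$r_d[1, 2], 0.3)
  expect_equal(dm$r_d[2, 1], 0.3)

  for (seed in 1:10) {
    set.seed(seed)
    dm <- structure(list(r_p = matrix(runif(36), 6), r_n = matrix(runif(36), 6),
                         r_d = NULL), class = "diffusion_matrix")
    dm <- symmetrize_diffusion(dm)
    expect_identical(dm$r_d, t(dm$r_d))
  }
})

test_that("diffusion graph recovers a noiseless toy at k = |E| and guards k", {
  g <- toy_graph()
  res <- diffuse_graph(g, diffusion_config(epsilon = 1e-12, max_iter = 2000))
  dg <- res$graph
  expect_equal(n_edges(dg), 2L)
  key <- function(gr) sort(paste(gr$edges$gene, gr$edges$phenotype,
                                 gr$edges$sign))
  expect_identical(key(dg), key(g))

  expect_error(diffusion_to_graph(res$matrix, g, k_edges = 0), ">= 1")

  zero <- structure(list(r_p = matrix(0, 3, 3), r_n = matrix(0, 3, 3),
                         r_d = matrix(0, 3, 3)), class = "diffusion_matrix")
  expect_warning(empty <- diffusion_to_graph(zero, g, 2), "no nonzero")
  expect_equal(n_edges(empty), 0L)

  expect_warning(all_nz <- diffusion_to_graph(res$matrix, g, 10^3),
                 "exceeds")
  expect_true(n_edges(all_nz) <= 2 * 1)
})

test_that("convergence deltas are non-increasing after the initial iterations", {
  g <- random_graph(6, 4, 18, 5)
  norm <- semi_row_normalize(adjacency(g))
  W <- gpsign:::srwr_mats(norm, diffusion_config())
  n <- 10
  q <- numeric(n); q[1] <- 1
  rp <- q; rm <- numeric(n)
  deltas <- numeric(40)
  for (i in 1:40) {
    rp2 <- W$Wpp %*% rp + W$Wpm %*% rm + 0.15 * q
    rm2 <- W$Wmp %*% rp + W$Wmm %*% rm
    deltas[i] <- sum(abs(rp2 - rp)) + sum(abs(rm2 - rm))
    rp <- rp2; rm <- rm2
  }
  expect_true(all(diff(deltas[-(1:5)]) <= 1e-15))
})
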