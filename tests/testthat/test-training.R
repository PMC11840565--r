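# Splitting, class-0 sampling, perturbation, metrics, training loop
# behaviour, projection fitting, prediction contracts.

test_that("edge split is exact, seeded, and a disjoint partition", {
  g <- random_graph(10, 6, 10, 1)
  sp <- split_edges(g, 0.8, 3)
  expect_equal(n_edges(sp$train), 8L)
  expect_equal(nrow(sp$test), 2L)
  sp2 <- split_edges(g, 0.8, 3)
  expect_identical(sp$train$edges, sp2$train$edges)

  for (seed in 1:10) {
    g <- random_graph(8, 5, 20, seed)
    sp <- split_edges(g, 0.75, seed)
    tr_keys <- paste(sp$train$gene_ids[sp$train$edges$gene],
                     sp$train$phenotype_ids[sp$train$edges$phenotype],
                     sp$train$edges$sign)
    te_keys <- paste(sp$test$gene, sp$test$phenotype, sp$test$sign)
    all_keys <- paste(g$gene_ids[g$edges$gene],
                      g$phenotype_ids[g$edges$phenotype], g$edges$sign)
    expect_setequal(c(tr_keys, te_keys), all_keys)
    expect_length(intersect(tr_keys, te_keys), 0)
    # train graph keeps all nodes
    expect_identical(sp$train$gene_ids, g$gene_ids)
  }
  expect_error(split_edges(g, 1.2, 1), "\\(0, 1\\)")
})

test_that("class-0 pairs avoid edges and excluded pairs, and are seeded", {
  for (seed in 1:20) {
    g <- random_graph(6, 5, 12, seed)
    p <- sample_class0_pairs(g, 8, seed)
    expect_false(any(gpsign:::edge_keys(g, p$gene, p$phenotype) %in%
                       gpsign:::edge_keys(g)))
  }
  g <- random_graph(6, 5, 12, 1)
  expect_identical(sample_class0_pairs(g, 8, 4), sample_class0_pairs(g, 8, 4))

  # exclusion list honoured
  ex <- data.frame(gene = rep(1:6, each = 5), phenotype = rep(1:5, 6))
  ex <- ex[!(gpsign:::edge_keys(g, ex$gene, ex$phenotype) %in%
               gpsign:::edge_keys(g)), ]
  keep <- ex[1:10, ]
  p <- sample_class0_pairs(g, 5, 1, exclude = keep[1:8, ])
  expect_false(any(gpsign:::edge_keys(g, p$gene, p$phenotype) %in%
                     gpsign:::edge_keys(g, keep$gene[1:8], keep$phenotype[1:8])))

  # complete bipartite graph has no non-edges
  full <- random_graph(3, 2, 6, 2)
  expect_warning(p0 <- sample_class0_pairs(full, 3, 1), "no non-edge")
  expect_equal(nrow(p0), 0L)

  # capping
  expect_warning(pc <- sample_class0_pairs(g, 10^4, 1), "capping")
  expect_equal(nrow(pc), 6 * 5 - n_edges(g))
})

test_that("sign perturbation flips an exact count and is an involution", {
  g <- random_graph(20, 5, 100, 3)
  expect_identical(perturb_signs(g, 0, 1)$edges, g$edges)
  p <- perturb_signs(g, 0.1, 7)
  expect_equal(sum(p$edges$sign != g$edges$sign), 10L)
  back <- perturb_signs(p, 0.1, 7)
  expect_identical(back$edges, g$edges)
})

test_that("edge subsampling keeps an exact uniform subset", {
  g <- random_graph(10, 5, 10, 4)
  expect_identical(subsample_edges(g, 1, 1)$edges, g$edges)
  s <- subsample_edges(g, 0.8, 2)
  expect_equal(n_edges(s), 8L)
  expect_true(all(paste(s$edges$gene, s$edges$phenotype, s$edges$sign) %in%
                    paste(g$edges$gene, g$edges$phenotype, g$edges$sign)))
})

test_that("rank AUC and average precision match independent references", {
  set.seed(8)
  truth <- c(rep(TRUE, 9), rep(FALSE, 11))[sample(20)]
  scores <- rnorm(20)

  # AUC against pROC (independent reference implementation)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(gpsign:::rank_auc(scores, truth), ref, tolerance = 1e-9)

  # average precision against a naive threshold loop
  ap_naive <- {
    ths <- sort(unique(scores), decreasing = TRUE)
    prev_rec <- 0; ap <- 0
    for (t in ths) {
      sel <- scores >= t
      prec <- sum(truth & sel) / sum(sel)
      rec <- sum(truth & sel) / sum(truth)
      ap <- ap + (rec - prev_rec) * prec
      prev_rec <- rec
    }
    ap
  }
  expect_equal(gpsign:::average_precision(scores, truth), ap_naive,
               tolerance = 1e-9)

  # perfect separation
  expect_equal(gpsign:::rank_auc(truth * 1, truth), 1)
  expect_equal(gpsign:::average_precision(truth * 1, truth), 1)
})

test_that("scores independent of labels give near-chance AUC over seeds", {
  aucs <- vapply(1:200, function(s) {
    set.seed(s)
    gpsign:::rank_auc(rnorm(40), rep(c(TRUE, FALSE), 20))
  }, 1)
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("training reduces the loss on a toy fixture and logs per term", {
  fx <- small_fit()
  lg <- fx$fit$log
  expect_true(all(c("epoch", "l_label", "l_inter", "l_intra", "l_cl",
                    "l_total") %in% names(lg)))
  expect_true(all(is.finite(lg$l_total)))
  expect_lt(lg$l_total[nrow(lg)], lg$l_total[1])
  # loss decreases over the first 10 epochs on the toy
  expect_lt(min(lg$l_total[1:10]) , lg$l_total[1] + 1e-12)
})

test_that("the no-CL ablation logs only label losses", {
  sim <- simulate_gp_graph(12, 3, 20, seed = 5)
  fit <- suppressWarnings(gpsign(sim$graph, sim$similarity, d = 4,
                                 epochs = 3, ablation = "no_cl", seed = 1))
  expect_true(all(is.na(fit$log$l_inter)))
  expect_true(all(is.na(fit$log$l_cl)))
  expect_true(all(is.finite(fit$log$l_label)))
  expect_equal(fit$log$l_total, fit$log$l_label)
})

test_that("training is seed-deterministic end to end", {
  sim <- simulate_gp_graph(12, 3, 20, seed = 6)
  f1 <- suppressWarnings(gpsign(sim$graph, sim$similarity, d = 4, epochs = 4,
                                seed = 3))
  f2 <- suppressWarnings(gpsign(sim$graph, sim$similarity, d = 4, epochs = 4,
                                seed = 3))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$z, f2$z)
})

test_that("projection fitting drives the MSE down and is idempotent", {
  fx <- small_fit()
  fit <- fit_projection(fx$fit, epochs = 4000, lr = 2e-2, seed = 2)
  expect_lt(fit$projection_mse, 1e-3)
  fit2 <- fit_projection(fx$fit, epochs = 4000, lr = 2e-2, seed = 2)
  expect_identical(fit$projection, fit2$projection)
  # projected TWAS-gene features approximate their embeddings
  X <- fit$features[fit$twas_genes, , drop = FALSE]
  expect_lt(projection_mse(X, fit$z[fit$twas_genes, ], fit$projection), 1e-3)
})

test_that("prediction emits normalized triples; unknown ids are fatal", {
  fx <- small_fit()
  fit <- fit_projection(fx$fit, seed = 1)
  pr <- predict(fit, fx$split$test)
  expect_equal(unname(pr$p_down + pr$p_none + pr$p_up),
               rep(1, nrow(pr)), tolerance = 1e-6)
  expect_true(all(pr$call %in% c("down", "none", "up")))

  expect_error(predict(fit, data.frame(gene = "nope", phenotype = "p01")),
               "unknown gene")
  expect_error(predict(fit, data.frame(gene = "g0001", phenotype = "nope")),
               "unknown phenotype")

  # batch equals per-pair prediction
  one_by_one <- do.call(rbind, lapply(seq_len(nrow(fx$split$test)), function(i)
    predict(fit, fx$split$test[i, ])))
  rownames(one_by_one) <- NULL
  expect_equal(pr, one_by_one, tolerance = 1e-12)

  # projection path differs from the trained-embedding path in general
  pr_proj <- predict(fit, fx$split$test, use_projection = TRUE)
  expect_false(isTRUE(all.equal(pr$p_up, pr_proj$p_up)))
})

test_that("evaluation reports all metrics in range and handles one-class sets", {
  fx <- small_fit()
  fit <- fit_projection(fx$fit, seed = 1)
  m <- evaluate_signs(fit, fx$split$test)
  for (nm in c("auc", "f1", "micro_f1", "macro_f1", "aupr", "precision")) {
    expect_gte(m[[nm]], 0)
    expect_lte(m[[nm]], 1)
  }
  expect_equal(m$n_test_edges, nrow(fx$split$test))

  one_class <- fx$split$test
  one_class$sign <- 1
  expect_warning(m1 <- evaluate_signs(fit, one_class), "single sign class")
  expect_equal(m1$auc, 0.5)
})

test_that("ablation variants share everything but the documented component", {
  sim <- simulate_gp_graph(12, 3, 20, seed = 7)
  fits <- lapply(c("full", "no_diffuse", "no_aug", "no_cl"), function(ab)
    suppressWarnings(gpsign(sim$graph, sim$similarity, d = 4, epochs = 3,
                            ablation = ab, seed = 1)))
  names(fits) <- c("full", "no_diffuse", "no_aug", "no_cl")
  # no_diffuse: the "diffusion" views come from the original graph
  expect_identical(fits$no_diffuse$diffusion_graph$edges,
                   sim$graph$edges)
  # full: a genuine diffusion graph is used
  expect_s3_class(fits$full$diffusion_graph, "sbgraph")
  # identical class-0 sampling and label setup across variants
  expect_identical(fits$full$class0_pairs, fits$no_cl$class0_pairs)
  # same parameter shapes everywhere
  expect_identical(lapply(fits$full$params, dim),
                   lapply(fits$no_aug$params, dim))
})

test_that("model checkpoints reload bit-exactly", {
  fx <- small_fit()
  f <- tempfile(fileext = ".rds")
  save_gpsign(fx$fit, f)
  back <- load_gpsign(f)
  expect_identical(back$params, fx$fit$params)
  expect_identical(back$z, fx$fit$z)
})
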