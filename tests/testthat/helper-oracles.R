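# Independent double-loop evaluators of the contrastive losses, used as
# oracles by the objective and acceptance tests.

# independent double-loop evaluators ---------------------------------------

brute_inter <- function(z_pos, z_neg, tau) {
  one <- function(zl) {
    n <- nrow(zl[[1]])
    tot <- 0; cnt <- 0
    for (k in 1:4) for (k2 in 1:4) {
      if (k == k2) next
      for (i in 1:n) {
        num <- exp(cosine_sim(zl[[k]][i, ], zl[[k2]][i, ]) / tau)
        den <- 0
        for (j in setdiff(1:n, i))
          den <- den + exp(cosine_sim(zl[[k]][i, ], zl[[k2]][j, ]) / tau)
        tot <- tot - log(num / den)
        cnt <- cnt + 1
      }
    }
    tot / cnt
  }
  one(z_pos) + one(z_neg)
}

brute_intra <- function(z, z_pos, z_neg, tau) {
  n <- nrow(z)
  tot <- 0
  for (i in 1:n) {
    num <- sum(vapply(1:4, function(m)
      exp(cosine_sim(z[i, ], z_pos[[m]][i, ]) / tau), 1))
    den <- sum(vapply(1:4, function(m)
      exp(cosine_sim(z[i, ], z_neg[[m]][i, ]) / tau), 1))
    tot <- tot - log(num / den)
  }
  tot / n
}

rand_embeds <- function(n, d, seed) {
  set.seed(seed)
  lapply(1:4, function(k) matrix(rnorm(n * d), n, d))
}
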