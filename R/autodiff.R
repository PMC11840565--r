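# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Values are always numeric matrices (column vectors are n x 1, scalars are
# 1 x 1).  A tape records nodes in creation order; ad_backward() seeds the
# loss gradient and sweeps the tape in reverse.  Each node carries a
# needs-gradient flag (`ng`) propagated from the parameter leaves, so
# backward work is skipped entirely on subgraphs that only depend on
# constants.  Only the operations the encoder and objectives need are
# implemented; each backward rule is the standard matrix-calculus adjoint.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp$params <- list()
  tp
}

ad_push <- function(tape, value, bw = NULL, ng = TRUE) {
  # force both promises before touching the tape counter: evaluating `value`
  # may itself push nodes (nested op calls), and R arguments are lazy
  force(value)
  force(bw)
  force(ng)
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$bw <- if (ng) bw else NULL
  nd$ng <- ng
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

as_mat <- function(v) {
  if (is.matrix(v)) v else matrix(v, ncol = 1)
}

ad_const <- function(tape, value) ad_push(tape, as_mat(value), ng = FALSE)

# A parameter node: a gradient-carrying leaf registered under `name`.
ad_param <- function(tape, name, value) {
  nd <- ad_push(tape, as_mat(value), ng = TRUE)
  tape$params[[name]] <- nd
  nd
}

acc_grad <- function(nd, g) {
  if (nd$ng) nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

ad_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1, 1)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  lapply(tape$params, function(p) p$grad)
}

ng2 <- function(x, y) x$ng || y$ng

# ---- arithmetic -----------------------------------------------------------

ad_add <- function(tape, x, y)
  ad_push(tape, x$value + y$value,
          function(g) { acc_grad(x, g); acc_grad(y, g) }, ng2(x, y))

ad_sub <- function(tape, x, y)
  ad_push(tape, x$value - y$value,
          function(g) { acc_grad(x, g); acc_grad(y, -g) }, ng2(x, y))

ad_mul <- function(tape, x, y)
  ad_push(tape, x$value * y$value,
          function(g) {
            if (x$ng) acc_grad(x, g * y$value)
            if (y$ng) acc_grad(y, g * x$value)
          }, ng2(x, y))

ad_div <- function(tape, x, y)
  ad_push(tape, x$value / y$value,
          function(g) {
            if (x$ng) acc_grad(x, g / y$value)
            if (y$ng) acc_grad(y, -g * x$value / (y$value^2))
          }, ng2(x, y))

ad_scale <- function(tape, x, k)
  ad_push(tape, k * x$value, function(g) acc_grad(x, k * g), x$ng)

ad_add_const <- function(tape, x, C)
  ad_push(tape, x$value + C, function(g) acc_grad(x, g), x$ng)

ad_sub_const <- function(tape, x, C)
  ad_push(tape, x$value - C, function(g) acc_grad(x, g), x$ng)

ad_mul_const <- function(tape, x, C)
  ad_push(tape, x$value * C, function(g) acc_grad(x, g * C), x$ng)

ad_matmul <- function(tape, x, y)
  ad_push(tape, x$value %*% y$value,
          function(g) {
            if (x$ng) acc_grad(x, tcrossprod(g, y$value))
            if (y$ng) acc_grad(y, crossprod(x$value, g))
          }, ng2(x, y))

ad_t <- function(tape, x)
  ad_push(tape, t(x$value), function(g) acc_grad(x, t(g)), x$ng)

# ---- indexing and aggregation --------------------------------------------

ad_gather_rows <- function(tape, x, idx) {
  idx <- as.integer(idx)
  ad_push(tape, x$value[idx, , drop = FALSE],
          function(g) {
            out <- matrix(0, nrow(x$value), ncol(x$value))
            rs <- rowsum(g, group = idx)
            out[as.integer(rownames(rs)), ] <- rs
            acc_grad(x, out)
          }, x$ng)
}

ad_scatter_rowsum <- function(tape, x, idx, n_out) {
  idx <- as.integer(idx)
  val <- matrix(0, n_out, ncol(x$value))
  rs <- rowsum(x$value, group = idx)
  val[as.integer(rownames(rs)), ] <- rs
  ad_push(tape, val, function(g) acc_grad(x, g[idx, , drop = FALSE]), x$ng)
}

ad_rowsums <- function(tape, x)
  ad_push(tape, matrix(rowSums(x$value), ncol = 1),
          function(g) acc_grad(x, matrix(g, nrow(x$value), ncol(x$value))),
          x$ng)

ad_sum <- function(tape, x)
  ad_push(tape, matrix(sum(x$value), 1, 1),
          function(g) acc_grad(x, matrix(g[1], nrow(x$value), ncol(x$value))),
          x$ng)

ad_mean <- function(tape, x) {
  n <- length(x$value)
  ad_push(tape, matrix(mean(x$value), 1, 1),
          function(g) acc_grad(x, matrix(g[1] / n, nrow(x$value), ncol(x$value))),
          x$ng)
}

ad_cbind <- function(tape, xs) {
  widths <- vapply(xs, function(x) ncol(x$value), 1L)
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ad_push(tape, do.call(cbind, lapply(xs, `[[`, "value")),
          function(g) {
            for (j in seq_along(xs))
              if (xs[[j]]$ng)
                acc_grad(xs[[j]], g[, starts[j]:ends[j], drop = FALSE])
          }, any(vapply(xs, `[[`, TRUE, "ng")))
}

# Extract the diagonal of a square matrix as a column vector.
ad_diag <- function(tape, x) {
  n <- nrow(x$value)
  ad_push(tape, matrix(diag(x$value), ncol = 1),
          function(g) {
            out <- matrix(0, n, n)
            diag(out) <- g
            acc_grad(x, out)
          }, x$ng)
}

# Multiply each row of x (n x d) by the matching entry of column vector v.
ad_rowscale <- function(tape, x, v)
  ad_push(tape, x$value * as.vector(v$value),
          function(g) {
            if (x$ng) acc_grad(x, g * as.vector(v$value))
            if (v$ng) acc_grad(v, matrix(rowSums(g * x$value), ncol = 1))
          }, ng2(x, v))

# Add bias row-vector b (1 x d) to every row of x (n x d).
ad_add_bias <- function(tape, x, b)
  ad_push(tape, sweep(x$value, 2, as.vector(b$value), "+"),
          function(g) {
            acc_grad(x, g)
            if (b$ng) acc_grad(b, matrix(colSums(g), nrow = 1))
          }, ng2(x, b))

# ---- nonlinearities -------------------------------------------------------

ad_exp <- function(tape, x) {
  e <- exp(x$value)
  ad_push(tape, e, function(g) acc_grad(x, g * e), x$ng)
}

ad_log <- function(tape, x)
  ad_push(tape, log(x$value), function(g) acc_grad(x, g / x$value), x$ng)

ad_clamp_min <- function(tape, x, eps)
  ad_push(tape, pmax(x$value, eps),
          function(g) acc_grad(x, g * (x$value > eps)), x$ng)

ad_relu <- function(tape, x)
  ad_push(tape, pmax(x$value, 0),
          function(g) acc_grad(x, g * (x$value > 0)), x$ng)

ad_leaky_relu <- function(tape, x, slope = 0.2) {
  pos <- x$value > 0
  ad_push(tape, x$value * (pos + slope * !pos),
          function(g) acc_grad(x, g * (pos + slope * !pos)), x$ng)
}

ad_elu <- function(tape, x) {
  pos <- x$value > 0
  e <- exp(pmin(x$value, 0))
  ad_push(tape, ifelse(pos, x$value, e - 1),
          function(g) acc_grad(x, g * ifelse(pos, 1, e)), x$ng)
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ad_push(tape, s, function(g) acc_grad(x, g * s * (1 - s)), x$ng)
}

# L2-normalize each row (rows with norm below eps are left divided by eps).
ad_row_l2_normalize <- function(tape, x, eps = 1e-12) {
  nrm <- pmax(sqrt(rowSums(x$value^2)), eps)
  y <- x$value / nrm
  ad_push(tape, y,
          function(g) {
            dots <- rowSums(g * x$value)
            acc_grad(x, g / nrm - x$value * (dots / nrm^3))
          }, x$ng)
}

# Fast row maxima (ties resolved to the first column, which is all a
# stabilization shift needs).
row_maxs <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, "first"))]

# Row-wise softmax with the usual max-subtraction stabilization (the
# subtracted row maxima are treated as constants, which leaves the gradient
# exact).
ad_softmax_rows <- function(tape, x) {
  m <- row_maxs(x$value)
  sh <- ad_sub_const(tape, x, matrix(m, nrow(x$value), ncol(x$value)))
  e <- ad_exp(tape, sh)
  ad_div(tape, e, ad_rep_cols(tape, ad_rowsums(tape, e), ncol(x$value)))
}

# Replicate a column vector across d columns.
ad_rep_cols <- function(tape, v, d)
  ad_push(tape, matrix(as.vector(v$value), nrow(v$value), d),
          function(g) acc_grad(v, matrix(rowSums(g), ncol = 1)), v$ng)

# ---- Adam optimizer -------------------------------------------------------

adam_new <- function(params, lr = 1e-3, weight_decay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     clip = 5) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$wd <- weight_decay
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$clip <- clip
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim(as_mat(p))))
  st$v <- st$m
  st
}

adam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  # global-norm gradient clipping stabilizes the attention encoder early on
  if (is.finite(st$clip)) {
    gn <- sqrt(sum(vapply(grads, function(g)
      if (is.null(g)) 0 else sum(g^2), 0)))
    if (gn > st$clip)
      grads <- lapply(grads, function(g) if (is.null(g)) g else g * (st$clip / gn))
  }
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- array(0, dim(as_mat(params[[nm]])))
    if (st$wd > 0) g <- g + st$wd * as_mat(params[[nm]])
    st$m[[nm]] <- st$beta1 * st$m[[nm]] + (1 - st$beta1) * g
    st$v[[nm]] <- st$beta2 * st$v[[nm]] + (1 - st$beta2) * g^2
    step <- st$lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + st$eps)
    params[[nm]] <- as_mat(params[[nm]]) - step
  }
  params
}
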