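# Readers and writers for the package's plain-text interchange formats:
# signed edge lists (TSV), BLAST outfmt-6 similarity, dense similarity
# matrices, and prediction tables.

#' Read a signed gene-phenotype edge list
#'
#' Reads a TSV with header columns `gene`, `phenotype` and either `zscore`
#' (TWAS z-score; the edge sign is its sign) or `sign` (literal +1/-1).
#' Node orderings follow first appearance in the file, giving a
#' deterministic node indexing.  Rows with a zero z-score carry no sign
#' information and are dropped with a warning; duplicated pairs with equal
#' sign are deduplicated (count reported via attribute), while conflicting
#' duplicate signs are an error.
#'
#' @param path file path.
#' @param sign_column `"auto"` (default: use whichever of `zscore`/`sign` is
#'   present), `"zscore"`, or `"sign"`.
#' @return list with `graph` (an [signed_bipartite_graph()]) and `twas`
#'   (data frame of retained `gene`, `phenotype`, `zscore` rows with
#'   attribute `twas_gene_set`).  The graph carries attributes
#'   `n_dropped_zero` and `n_deduplicated`.
#' @export
read_edge_list <- function(path, sign_column = c("auto", "zscore", "sign")) {
  sign_column <- match.arg(sign_column)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("gene", "phenotype") %in% names(df)))
    stopf("edge list %s lacks gene/phenotype columns", path)
  col <- switch(sign_column,
    auto = if ("zscore" %in% names(df)) "zscore"
           else if ("sign" %in% names(df)) "sign"
           else stopf("edge list %s has neither zscore nor sign column", path),
    zscore = "zscore", sign = "sign")
  if (!col %in% names(df)) stopf("edge list %s lacks column %s", path, col)
  z <- suppressWarnings(as.numeric(df[[col]]))
  if (anyNA(z) && nrow(df))
    stopf("non-numeric %s value at row %d of %s", col, which(is.na(z))[1], path)

  n_zero <- sum(z == 0)
  if (n_zero) {
    warnf("%d row(s) with zero %s dropped (no sign information)", n_zero, col)
    keep <- z != 0
    df <- df[keep, , drop = FALSE]
    z <- z[keep]
  }
  gene_ids <- unique(df$gene)
  phen_ids <- unique(df$phenotype)
  sg <- as.integer(sign(z))

  # pair-level dedup: identical signs collapse, conflicts are fatal
  key <- paste(df$gene, df$phenotype, sep = "\r")
  n_dedup <- 0L
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      if (length(unique(sg[idx])) > 1L)
        stopf("conflicting signs for pair (%s, %s)",
              df$gene[idx[1]], df$phenotype[idx[1]])
    }
    dup <- duplicated(key)
    n_dedup <- sum(dup)
    df <- df[!dup, , drop = FALSE]
    z <- z[!dup]
    sg <- sg[!dup]
  }

  graph <- signed_bipartite_graph(
    gene_ids, phen_ids,
    data.frame(gene = df$gene, phenotype = df$phenotype, sign = sg))
  attr(graph, "n_dropped_zero") <- n_zero
  attr(graph, "n_deduplicated") <- n_dedup
  twas <- data.frame(gene = df$gene, phenotype = df$phenotype,
                     zscore = z, stringsAsFactors = FALSE)
  attr(twas, "twas_gene_set") <- unique(twas$gene)
  list(graph = graph, twas = twas)
}

#' Write a signed edge list
#'
#' Inverse of [read_edge_list()]: emits a TSV with header
#' `gene phenotype zscore` (if `zscores` given) or `gene phenotype sign`.
#'
#' @param graph an `sbgraph`.
#' @param path output file path.
#' @param zscores optional numeric vector aligned with `graph$edges` rows.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path, zscores = NULL) {
  e <- graph$edges
  out <- data.frame(gene = graph$gene_ids[e$gene],
                    phenotype = graph$phenotype_ids[e$phenotype])
  if (is.null(zscores)) out$sign <- e$sign else out$zscore <- zscores
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene similarity matrix container
#'
#' Validates and wraps a dense gene-gene similarity matrix whose row `i`
#' supplies the initial feature vector of gene `i`.  Entries must lie in
#' `[0, 1]`, the matrix must be symmetric (within 1e-12) and the diagonal
#' must equal 1.
#'
#' @param matrix square numeric matrix.
#' @param gene_order character identifiers matching the rows.
#' @return object of class `"gene_similarity"`.
#' @export
gene_similarity <- function(matrix, gene_order) {
  matrix <- as.matrix(matrix)
  gene_order <- as.character(gene_order)
  if (nrow(matrix) != ncol(matrix)) stopf("similarity matrix must be square")
  if (nrow(matrix) != length(gene_order))
    stopf("gene_order length does not match matrix dimension")
  if (any(matrix < -1e-12) || any(matrix > 1 + 1e-12))
    stopf("similarity values must lie in [0, 1]")
  if (max(abs(matrix - t(matrix))) > 1e-12)
    stopf("similarity matrix must be symmetric (within 1e-12)")
  if (any(abs(diag(matrix) - 1) > 1e-12))
    stopf("similarity diagonal must equal 1")
  dimnames(matrix) <- list(gene_order, gene_order)
  structure(list(matrix = matrix, gene_order = gene_order),
            class = "gene_similarity")
}

#' @export
print.gene_similarity <- function(x, ...) {
  cat(sprintf("Gene similarity matrix: %d genes, mean off-diagonal %.3f\n",
              length(x$gene_order),
              mean(x$matrix[upper.tri(x$matrix)])))
  invisible(x)
}

#' Build a gene similarity matrix from BLAST tabular output
#'
#' Consumes 12-column BLAST outfmt-6 rows (`qseqid sseqid pident ...
#' bitscore`).  The default score for a pair is the best hit's percent
#' identity divided by 100; `score = "bitscore"` instead uses bitscores
#' normalized by the largest bitscore in the file.  The matrix is
#' symmetrized by the elementwise maximum with its transpose, the diagonal
#' is forced to 1, and pairs without hits score 0.
#'
#' @param path BLAST tabular file (no header).
#' @param gene_order character vector fixing row/column order.
#' @param score `"pident"` (default) or `"bitscore"`.
#' @return a [gene_similarity()] object.
#' @export
read_blast_similarity <- function(path, gene_order,
                                  score = c("pident", "bitscore")) {
  score <- match.arg(score)
  gene_order <- as.character(gene_order)
  n <- length(gene_order)
  M <- matrix(0, n, n)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 12L))
      stopf("malformed BLAST tabular row at line %d (expected 12 columns, got %d)",
            which(nf < 12L)[1], nf[which(nf < 12L)[1]])
    q <- vapply(fields, `[[`, "", 1L)
    s <- vapply(fields, `[[`, "", 2L)
    pid <- as.numeric(vapply(fields, `[[`, "", 3L))
    bit <- as.numeric(vapply(fields, `[[`, "", 12L))
    if (anyNA(pid) || anyNA(bit))
      stopf("malformed BLAST tabular row at line %d (non-numeric score)",
            which(is.na(pid) | is.na(bit))[1])
    qi <- match(q, gene_order)
    si <- match(s, gene_order)
    unknown <- is.na(qi) | is.na(si)
    if (any(unknown)) {
      warnf("%d BLAST hit(s) referencing genes outside gene_order skipped",
            sum(unknown))
      qi <- qi[!unknown]; si <- si[!unknown]
      pid <- pid[!unknown]; bit <- bit[!unknown]
    }
    val <- switch(score,
                  pident = pid / 100,
                  bitscore = if (length(bit)) bit / max(bit) else numeric())
    for (h in seq_along(qi)) {
      if (val[h] > M[qi[h], si[h]]) M[qi[h], si[h]] <- val[h]
    }
  }
  M <- pmax(M, t(M))
  M <- clamp01(M)
  diag(M) <- 1
  gene_similarity(M, gene_order)
}

#' Read a dense labelled similarity matrix (TSV)
#'
#' @param path TSV with row and column gene labels.
#' @return a [gene_similarity()] object.
#' @export
read_similarity_matrix <- function(path) {
  M <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  if (!identical(rownames(M), colnames(M)))
    stopf("similarity matrix row and column labels differ")
  gene_similarity(M, rownames(M))
}

#' Write a dense similarity matrix (TSV)
#' @param sim a `gene_similarity`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sim, path) {
  utils::write.table(data.frame(gene = sim$gene_order, sim$matrix,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Argmax call with the conservative tie-break none > up > down.
call_from_probs <- function(p_down, p_none, p_up) {
  P <- cbind(none = p_none, up = p_up, down = p_down)
  colnames(P)[max.col(P, ties.method = "first")]
}

#' Write prediction rows with probability triples and calls
#'
#' Each row carries the three association probabilities (down / none / up)
#' which must sum to 1 within 1e-6; the `call` column is the argmax label
#' with ties broken conservatively in favour of `none`, then `up`, then
#' `down`.
#'
#' @param rows data frame with columns `gene`, `phenotype`, `p_down`,
#'   `p_none`, `p_up`.
#' @param path output TSV path.
#' @return the augmented data frame (with `call`), invisibly.
#' @export
write_predictions <- function(rows, path) {
  need <- c("gene", "phenotype", "p_down", "p_none", "p_up")
  if (!all(need %in% names(rows)))
    stopf("prediction rows need columns %s", paste(need, collapse = ", "))
  tot <- rows$p_down + rows$p_none + rows$p_up
  if (any(abs(tot - 1) > 1e-6))
    stopf("probability triple does not sum to 1 (row %d: %.8f)",
          which(abs(tot - 1) > 1e-6)[1], tot[which(abs(tot - 1) > 1e-6)[1]])
  out <- rows[need]
  out$call <- call_from_probs(rows$p_down, rows$p_none, rows$p_up)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
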