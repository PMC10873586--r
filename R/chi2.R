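#' One-vs-rest label binarization
#'
#' Recasts a multi-class label vector as a binary problem for one target
#' type: 1 where the label equals `target`, 0 elsewhere.
#'
#' @param labels Character vector of per-cell types.
#' @param target The cell type treated as the positive class.
#' @return Integer 0/1 vector with at least one positive and one negative.
#' @export
binarize_labels <- function(labels, target) {
  labels <- as.character(labels)
  y <- as.integer(labels == target)
  if (sum(y) == 0) stop("target cell type not present: ", target, call. = FALSE)
  if (all(y == 1)) stop("degenerate split: all cells are '", target, "'",
                        call. = FALSE)
  y
}

#' Per-gene chi-squared feature scores
#'
#' Frequency-based chi-squared statistic over class-wise value sums (the
#' formulation used by the standard feature-selection implementations in
#' this method's ecosystem). For gene j with class-wise observed sums
#' \eqn{O_c = \sum_{i: y_i = c} x_{ij}}, class counts \eqn{N_c},
#' \eqn{n = N_0 + N_1}, gene total \eqn{T_j}, and expected
#' \eqn{E_c = T_j N_c / n}:
#' \deqn{score_j = \sum_c (O_c - E_c)^2 / E_c.}
#' Genes with zero total score 0 by convention. Values must be
#' non-negative (normalized, optionally log1p-transformed expression
#' qualifies).
#'
#' @param matrix Non-negative cells x genes numeric matrix (dense or
#'   sparse).
#' @param y Binary 0/1 vector, one entry per row, both classes present.
#' @return Numeric vector of per-gene scores (length = number of genes).
#' @export
chi2_scores <- function(matrix, y) {
  y <- as.integer(y)
  stopifnot(length(y) == nrow(matrix), all(y %in% c(0L, 1L)))
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("y must contain both classes", call. = FALSE)
  }
  vals <- if (is(matrix, "sparseMatrix")) matrix@x else matrix
  if (length(vals) && any(vals < 0)) {
    stop("chi-squared requires non-negative features", call. = FALSE)
  }
  n <- length(y)
  n1 <- sum(y)
  n0 <- n - n1
  o1 <- as.numeric(Matrix::colSums(matrix[y == 1L, , drop = FALSE]))
  tot <- as.numeric(Matrix::colSums(matrix))
  o0 <- tot - o1
  e1 <- tot * n1 / n
  e0 <- tot * n0 / n
  score <- ifelse(tot > 0, (o1 - e1)^2 / e1 + (o0 - e0)^2 / e0, 0)
  unname(score)
}

#' Select per-type gene signatures by one-vs-rest chi-squared
#'
#' For each cell type in the codebook, builds the one-vs-rest binary
#' problem, scores every gene with [chi2_scores()], and keeps the top
#' `min(k, m)` genes ranked by descending score (ties broken by
#' lexicographic gene id so the selection is deterministic across
#' platforms). Signatures may overlap across types; no de-duplication is
#' performed.
#'
#' @param data A labeled (and typically normalized) `expression_dataset`.
#' @param k Number of genes to keep per type (default 300).
#' @return A `signature_set`: list with `per_type` (type -> ordered
#'   gene-id vector), `scores` (type -> full named score vector, for
#'   audit), and `k`.
#' @export
select_signatures <- function(data, k = 300L) {
  stopifnot(inherits(data, "expression_dataset"), k >= 1)
  types <- label_codebook(data)
  k <- as.integer(k)
  m <- n_genes(data)
  take <- min(k, m)
  per_type <- list()
  scores <- list()
  for (ty in types) {
    y <- binarize_labels(data$labels, ty)
    s <- chi2_scores(data$matrix, y)
    ord <- order(-s, data$gene_ids, method = "radix")
    per_type[[ty]] <- data$gene_ids[ord[seq_len(take)]]
    scores[[ty]] <- setNames(s, data$gene_ids)
  }
  structure(list(per_type = per_type, scores = scores, k = k),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set: ", length(x$per_type), " cell types, k=", x$k,
      " genes per type\n", sep = "")
  for (ty in names(x$per_type)) {
    g <- x$per_type[[ty]]
    cat("  ", ty, ": ", length(g), " genes (",
        paste(head(g, 4), collapse = ", "),
        if (length(g) > 4) ", ..." else "", ")\n", sep = "")
  }
  invisible(x)
}

#' Write / read a signature set as TSV
#'
#' Columns: cell_type, rank, gene_id, chi2_score.
#'
#' @param signatures A `signature_set`.
#' @param path Output TSV path.
#' @return `read_signatures` returns a `signature_set` (scores restricted
#'   to the selected genes).
#' @export
write_signatures <- function(signatures, path) {
  stopifnot(inherits(signatures, "signature_set"))
  rows <- do.call(rbind, lapply(names(signatures$per_type), function(ty) {
    g <- signatures$per_type[[ty]]
    data.frame(cell_type = ty, rank = seq_along(g), gene_id = g,
               chi2_score = unname(signatures$scores[[ty]][g]),
               stringsAsFactors = FALSE)
  }))
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- data.table::fread(path, sep = "\t", data.table = FALSE,
                           colClasses = list(character = c("cell_type", "gene_id")))
  per_type <- list()
  scores <- list()
  for (ty in unique(tab$cell_type)) {
    sub <- tab[tab$cell_type == ty, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    per_type[[ty]] <- sub$gene_id
    scores[[ty]] <- setNames(sub$chi2_score, sub$gene_id)
  }
  structure(list(per_type = per_type, scores = scores,
                 k = max(vapply(per_type, length, integer(1)))),
            class = "signature_set")
}
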