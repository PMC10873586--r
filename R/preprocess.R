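#' Preprocessing settings
#'
#' Settings for per-cell total-count normalization. Each cell's expression
#' vector is divided by its total and multiplied by `target_scale`
#' (counts-per-`target_scale`), optionally followed by log(1 + x). An
#' optional minimal gene filter removes genes detected in fewer than
#' `min_cells_per_gene` cells. Training and test data are always processed
#' separately: no statistic is shared between them.
#'
#' @param target_scale Positive scale each cell is normalized to
#'   (default 1e4, the conventional counts-per-ten-thousand target).
#' @param log_transform Apply log1p after scaling (default TRUE).
#' @param apply_gene_filter Drop rarely detected genes (default FALSE).
#' @param min_cells_per_gene Detection threshold for the gene filter.
#' @param drop_empty_cells If TRUE, cells with all-zero expression are
#'   dropped with a warning; if FALSE (default) they raise an error naming
#'   the offending cell.
#' @return A `preprocess_settings` list.
#' @export
preprocess_settings <- function(target_scale = 1e4,
                                log_transform = TRUE,
                                apply_gene_filter = FALSE,
                                min_cells_per_gene = 3L,
                                drop_empty_cells = FALSE) {
  stopifnot(is.numeric(target_scale), length(target_scale) == 1,
            target_scale > 0, min_cells_per_gene >= 0)
  structure(list(target_scale = target_scale,
                 log_transform = isTRUE(log_transform),
                 apply_gene_filter = isTRUE(apply_gene_filter),
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 drop_empty_cells = isTRUE(drop_empty_cells)),
            class = "preprocess_settings")
}

#' Per-cell total-count normalization
#'
#' Divides each cell's values by that cell's total and multiplies by
#' `settings$target_scale`, so every row sums to `target_scale`;
#' optionally log1p-transformed afterwards. Applied independently per
#' cell, so it commutes with any reordering of cells.
#'
#' @param data An `expression_dataset` with non-negative values.
#' @param settings A [preprocess_settings()] object.
#' @return A normalized `expression_dataset` (labels/batch carried
#'   through; cells possibly dropped if `drop_empty_cells`).
#' @export
normalize_cells <- function(data, settings = preprocess_settings()) {
  stopifnot(inherits(data, "expression_dataset"),
            inherits(settings, "preprocess_settings"))
  if (settings$apply_gene_filter) {
    detected <- Matrix::colSums(data$matrix > 0)
    keep <- detected >= settings$min_cells_per_gene
    if (!all(keep)) data <- data[, which(keep)]
    if (n_genes(data) == 0) stop("gene filter removed all genes", call. = FALSE)
  }
  totals <- Matrix::rowSums(data$matrix)
  empty <- totals == 0
  if (any(empty)) {
    if (!settings$drop_empty_cells) {
      stop("all-zero cell(s): ",
           paste(head(data$cell_ids[empty], 5), collapse = ", "),
           call. = FALSE)
    }
    warning(sum(empty), " all-zero cell(s) dropped", call. = FALSE)
    data <- data[which(!empty), ]
    totals <- totals[!empty]
  }
  scale <- settings$target_scale / totals
  m <- if (is(data$matrix, "sparseMatrix")) {
    Matrix::Diagonal(x = scale) %*% data$matrix
  } else {
    data$matrix * scale
  }
  if (settings$log_transform) m <- log1p(m)
  if (is(m, "Matrix") && !is(m, "dgCMatrix") && !is.matrix(data$matrix)) {
    m <- as(m, "CsparseMatrix")
  }
  expression_dataset(m, gene_ids = data$gene_ids, cell_ids = data$cell_ids,
                     labels = data$labels, batch = data$batch)
}

#' Align a dataset onto a reference gene space
#'
#' Reorders (and if necessary zero-fills) the columns of `test` so that
#' they are exactly `train_genes`, in that order. Genes absent from the
#' test data are filled with `fill` and reported in a warning; extra test
#' genes are dropped. Needed whenever a model trained on one gene space is
#' applied to data measured on another (inter-dataset and cross-species
#' prediction).
#'
#' @param train_genes Non-empty character vector of reference gene ids.
#' @param test An `expression_dataset`.
#' @param fill Value for missing genes (default 0).
#' @return An `expression_dataset` with columns `train_genes`.
#' @export
align_genes <- function(train_genes, test, fill = 0) {
  stopifnot(length(train_genes) > 0, inherits(test, "expression_dataset"))
  train_genes <- as.character(train_genes)
  idx <- match(train_genes, test$gene_ids)
  if (all(is.na(idx))) stop("disjoint gene spaces", call. = FALSE)
  n_missing <- sum(is.na(idx))
  sparse <- is(test$matrix, "sparseMatrix")
  if (n_missing == 0L) {
    m <- test$matrix[, idx, drop = FALSE]
  } else {
    warning(n_missing, " gene", if (n_missing > 1) "s", " imputed with fill=",
            fill, call. = FALSE)
    if (sparse && fill == 0) {
      m <- Matrix::Matrix(0, nrow = n_cells(test), ncol = length(train_genes),
                          sparse = TRUE)
      m <- as(m, "CsparseMatrix")
    } else {
      m <- matrix(fill, nrow = n_cells(test), ncol = length(train_genes))
    }
    present <- !is.na(idx)
    m[, which(present)] <- test$matrix[, idx[present], drop = FALSE]
  }
  expression_dataset(m, gene_ids = train_genes, cell_ids = test$cell_ids,
                     labels = test$labels, batch = test$batch)
}
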