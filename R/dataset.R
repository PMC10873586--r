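#' Construct an expression dataset
#'
#' The shared container used throughout the package: a non-negative
#' cells x genes expression matrix (dense or \pkg{Matrix} sparse) together
#' with unique gene and cell identifiers, optional per-cell type labels and
#' optional per-cell batch labels.
#'
#' @param matrix Numeric cells x genes matrix (base matrix or a
#'   \pkg{Matrix} sparse matrix). Rows are cells, columns are genes. All
#'   entries must be finite and non-negative.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column.
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#' @param labels Optional character vector of per-cell cell-type labels.
#' @param batch Optional character vector of per-cell batch labels.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix`, `gene_ids`, `cell_ids`, `labels`, `batch`.
#'
#' @examples
#' m <- matrix(rpois(12, 5), nrow = 3,
#'             dimnames = list(NULL, NULL))
#' d <- expression_dataset(m, gene_ids = paste0("g", 1:4),
#'                         cell_ids = paste0("c", 1:3),
#'                         labels = c("A", "A", "B"))
#' d
#' @export
expression_dataset <- function(matrix, gene_ids, cell_ids,
                               labels = NULL, batch = NULL) {
  if (!(is.matrix(matrix) || is(matrix, "Matrix"))) {
    stop("`matrix` must be a base matrix or a Matrix sparse matrix",
         call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(matrix) != length(cell_ids)) {
    stop("matrix has ", nrow(matrix), " rows but ", length(cell_ids),
         " cell ids", call. = FALSE)
  }
  if (ncol(matrix) != length(gene_ids)) {
    stop("matrix has ", ncol(matrix), " columns but ", length(gene_ids),
         " gene ids", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene id", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("duplicate cell id", call. = FALSE)
  vals <- if (is(matrix, "sparseMatrix")) matrix@x else matrix
  if (length(vals) && (any(!is.finite(vals)) || any(vals < 0))) {
    stop("matrix entries must be finite and non-negative", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(cell_ids)) {
      stop("labels must have one entry per cell", call. = FALSE)
    }
  }
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (length(batch) != length(cell_ids)) {
      stop("batch must have one entry per cell", call. = FALSE)
    }
  }
  dimnames(matrix) <- list(cell_ids, gene_ids)
  structure(list(matrix = matrix, gene_ids = gene_ids, cell_ids = cell_ids,
                 labels = labels, batch = batch),
            class = "expression_dataset")
}

#' Number of cells / genes in a dataset
#' @param data An `expression_dataset`.
#' @return Integer count.
#' @export
n_cells <- function(data) length(data$cell_ids)

#' @rdname n_cells
#' @export
n_genes <- function(data) length(data$gene_ids)

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset: ", n_cells(x), " cells x ", n_genes(x),
      " genes\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels: ", length(tab), " types (",
        paste0(names(tab), "=", tab, collapse = ", "), ")\n", sep = "")
  }
  if (!is.null(x$batch)) {
    cat("  batches: ", paste(sort_c(unique(x$batch)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Subset an expression dataset
#'
#' Row (cell) and column (gene) subsetting that keeps the identifier
#' vectors and per-cell annotations aligned with the matrix.
#'
#' @param x An `expression_dataset`.
#' @param i Cell index (integer, logical, or cell-id character vector).
#' @param j Gene index (integer, logical, or gene-id character vector).
#' @param ... Unused.
#' @return An `expression_dataset`.
#' @export
`[.expression_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_cells(x))
  if (missing(j)) j <- seq_len(n_genes(x))
  if (is.character(i)) i <- match(i, x$cell_ids)
  if (is.character(j)) j <- match(j, x$gene_ids)
  if (anyNA(i)) stop("unknown cell id", call. = FALSE)
  if (anyNA(j)) stop("unknown gene id", call. = FALSE)
  expression_dataset(
    x$matrix[i, j, drop = FALSE],
    gene_ids = x$gene_ids[j],
    cell_ids = x$cell_ids[i],
    labels = if (!is.null(x$labels)) x$labels[i],
    batch = if (!is.null(x$batch)) x$batch[i]
  )
}

#' Label codebook: the ordered set of cell types
#'
#' The deterministic (C-locale lexicographic) ordering of the distinct
#' cell-type labels. All class-probability outputs in the package order
#' their columns by this codebook.
#'
#' @param labels Character vector of cell-type labels (or an
#'   `expression_dataset` with labels).
#' @return Character vector of t >= 2 unique type names, sorted.
#' @export
label_codebook <- function(labels) {
  if (inherits(labels, "expression_dataset")) labels <- labels$labels
  if (is.null(labels)) stop("dataset has no labels", call. = FALSE)
  types <- sort_c(unique(as.character(labels)))
  if (length(types) < 2) {
    stop("label codebook requires at least 2 cell types", call. = FALSE)
  }
  types
}

#' Pool several labeled datasets over their common gene space
#'
#' Used by the inter-dataset protocol: training datasets are concatenated
#' over the intersection of their gene spaces (a union would require
#' imputing values inside training data).
#'
#' @param datasets List of `expression_dataset` objects with labels.
#' @return A single `expression_dataset`.
#' @export
pool_datasets <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  if (length(datasets) == 1) return(datasets[[1]])
  genes <- Reduce(intersect, lapply(datasets, function(d) d$gene_ids))
  if (length(genes) == 0) stop("disjoint gene spaces", call. = FALSE)
  genes <- sort_c(genes)
  parts <- lapply(datasets, function(d) d[, genes])
  mats <- lapply(parts, function(d) d$matrix)
  dense <- any(vapply(mats, is.matrix, logical(1)))
  m <- if (dense) do.call(rbind, lapply(mats, as.matrix)) else do.call(rbind, mats)
  expression_dataset(
    m,
    gene_ids = genes,
    cell_ids = unlist(lapply(parts, function(d) d$cell_ids), use.names = FALSE),
    labels = unlist(lapply(parts, function(d) d$labels), use.names = FALSE),
    batch = {
      b <- lapply(parts, function(d) d$batch)
      if (all(vapply(b, is.null, logical(1)))) NULL else {
        unlist(lapply(seq_along(parts), function(k) {
          if (is.null(b[[k]])) rep(paste0("dataset", k), n_cells(parts[[k]]))
          else b[[k]]
        }), use.names = FALSE)
      }
    }
  )
}
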