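#' Read an expression dataset from disk
#'
#' Three on-disk conventions are supported:
#' \describe{
#'   \item{`"mtx"`}{Matrix Market triplet file with `genes.tsv` and
#'     `barcodes.tsv` sidecars (10x convention: the matrix on disk is
#'     genes x cells and is transposed on read). `path` may be the
#'     directory or the `.mtx` file itself.}
#'   \item{`"dense"`}{Delimited text (CSV/TSV inferred from the
#'     extension): header row of gene ids, first column of cell ids.
#'     Set `cells_in_rows = FALSE` when the file is genes x cells
#'     (header = cell ids, first column = gene ids).}
#'   \item{`"h5ad"`}{HDF5 annotated-matrix container with an h5ad-
#'     compatible layout: `X` dense or CSR/CSC sparse, `obs/_index`,
#'     `var/_index`, optional `obs/cell_type` and `obs/batch` columns
#'     (plain or categorical).}
#' }
#' Labels may come from a 2-column TSV (`cell_id`, `cell_type`) given as
#' `labels_path`; every cell id in it must exist in the matrix.
#'
#' @param path File or directory path.
#' @param format One of `"mtx"`, `"dense"`, `"h5ad"`.
#' @param labels_path Optional label TSV path.
#' @param cells_in_rows Dense orientation flag (default TRUE, i.e. the
#'   file is cells x genes).
#' @return A validated `expression_dataset`.
#' @export
read_dataset <- function(path, format = c("mtx", "dense", "h5ad"),
                         labels_path = NULL, cells_in_rows = TRUE) {
  format <- match.arg(format)
  data <- switch(format,
                 mtx = read_mtx_dir(path),
                 dense = read_dense(path, cells_in_rows),
                 h5ad = read_h5ad(path))
  if (!is.null(labels_path)) {
    lab <- read_labels(labels_path)
    miss <- setdiff(names(lab), data$cell_ids)
    if (length(miss)) {
      stop("unknown cell id in label table: ",
           paste(head(miss, 5), collapse = ", "), call. = FALSE)
    }
    labels <- unname(lab[data$cell_ids])
    if (anyNA(labels)) {
      stop("label table does not cover every cell", call. = FALSE)
    }
    data$labels <- labels
  }
  data
}

read_mtx_dir <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
  } else {
    mtx <- path
    path <- dirname(path)
  }
  genes_f <- file.path(path, "genes.tsv")
  cells_f <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, genes_f, cells_f)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  m <- Matrix::readMM(mtx)  # genes x cells on disk
  genes <- data.table::fread(genes_f, header = FALSE, sep = "\t",
                             data.table = FALSE)[[1]]
  cells <- data.table::fread(cells_f, header = FALSE, sep = "\t",
                             data.table = FALSE)[[1]]
  expression_dataset(as(Matrix::t(m), "CsparseMatrix"),
                     gene_ids = genes, cell_ids = cells)
}

read_dense <- function(path, cells_in_rows) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  row_ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  col_ids <- colnames(m)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  if (cells_in_rows) {
    expression_dataset(m, gene_ids = col_ids, cell_ids = row_ids)
  } else {
    expression_dataset(t(m), gene_ids = row_ids, cell_ids = col_ids)
  }
}

h5_string_col <- function(x) {
  if (is.list(x)) as.character(x$categories)[as.integer(x$codes) + 1L]
  else as.character(x)
}

read_h5ad <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ls <- rhdf5::h5ls(path)
  cells <- as.character(rhdf5::h5read(path, "obs/_index"))
  genes <- as.character(rhdf5::h5read(path, "var/_index"))
  x_is_group <- any(ls$group == "/X")
  if (x_is_group) {
    att <- rhdf5::h5readAttributes(path, "X")
    shape <- as.integer(att$shape)  # (n_obs, n_vars)
    dat <- as.numeric(rhdf5::h5read(path, "X/data"))
    idx <- as.integer(rhdf5::h5read(path, "X/indices"))
    ptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    enc <- as.character(att[["encoding-type"]])
    if (identical(enc, "csr_matrix")) {
      rows <- rep(seq_len(shape[1]), diff(ptr))
      m <- Matrix::sparseMatrix(i = rows, j = idx + 1L, x = dat,
                                dims = shape)
    } else if (identical(enc, "csc_matrix")) {
      cols <- rep(seq_len(shape[2]), diff(ptr))
      m <- Matrix::sparseMatrix(i = idx + 1L, j = cols, x = dat,
                                dims = shape)
    } else {
      stop("unsupported sparse encoding: ", enc, call. = FALSE)
    }
  } else {
    m <- t(rhdf5::h5read(path, "X"))  # stored obs x var, read transposed
  }
  obs_cols <- ls$name[ls$group == "/obs"]
  labels <- if ("cell_type" %in% obs_cols) {
    h5_string_col(rhdf5::h5read(path, "obs/cell_type"))
  } else NULL
  batch <- if ("batch" %in% obs_cols) {
    h5_string_col(rhdf5::h5read(path, "obs/batch"))
  } else NULL
  rhdf5::h5closeAll()
  expression_dataset(m, gene_ids = genes, cell_ids = cells,
                     labels = labels, batch = batch)
}

#' Write an expression dataset to disk
#'
#' Inverse of [read_dataset()] for each format; write-then-read
#' reproduces the matrix to full precision with identical id order.
#' For `"mtx"`, `path` is a directory receiving `matrix.mtx`,
#' `genes.tsv`, `barcodes.tsv` and (when labels are present)
#' `labels.tsv`. For `"dense"`, a single cells x genes CSV/TSV. For
#' `"h5ad"`, an anndata-compatible HDF5 file with dense `X`.
#'
#' @param data An `expression_dataset`.
#' @param path Output path (directory for `"mtx"`).
#' @param format One of `"mtx"`, `"dense"`, `"h5ad"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, format = c("mtx", "dense", "h5ad")) {
  stopifnot(inherits(data, "expression_dataset"))
  format <- match.arg(format)
  switch(format,
    mtx = {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      m <- as(Matrix::t(Matrix::Matrix(data$matrix, sparse = TRUE)),
              "CsparseMatrix")
      Matrix::writeMM(m, file.path(path, "matrix.mtx"))
      writeLines(data$gene_ids, file.path(path, "genes.tsv"))
      writeLines(data$cell_ids, file.path(path, "barcodes.tsv"))
      if (!is.null(data$labels)) {
        write_labels(setNames(data$labels, data$cell_ids),
                     file.path(path, "labels.tsv"))
      }
    },
    dense = {
      sep <- if (grepl("\\.tsv$", path)) "\t" else ","
      df <- data.frame(cell_id = data$cell_ids,
                       as.matrix(data$matrix), check.names = FALSE)
      colnames(df) <- c("cell_id", data$gene_ids)
      data.table::fwrite(df, path, sep = sep)
    },
    h5ad = {
      if (file.exists(path)) unlink(path)
      rhdf5::h5createFile(path)
      # stored transposed so h5py/anndata sees shape (n_obs, n_vars)
      rhdf5::h5write(t(as.matrix(data$matrix)), path, "X")
      rhdf5::h5createGroup(path, "obs")
      rhdf5::h5createGroup(path, "var")
      rhdf5::h5write(data$cell_ids, path, "obs/_index")
      rhdf5::h5write(data$gene_ids, path, "var/_index")
      if (!is.null(data$labels)) rhdf5::h5write(data$labels, path, "obs/cell_type")
      if (!is.null(data$batch)) rhdf5::h5write(data$batch, path, "obs/batch")
      h5_annotate_anndata(path, data)
      rhdf5::h5closeAll()
    })
  invisible(path)
}

# Minimal attribute decoration so python anndata can open the file.
h5_annotate_anndata <- function(path, data) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  wa <- function(obj, name, value, asScalar = TRUE) {
    rhdf5::h5writeAttribute(value, obj, name, asScalar = asScalar,
                            variableLengthString = TRUE, encoding = "UTF-8")
  }
  xd <- rhdf5::H5Dopen(fid, "X")
  wa(xd, "encoding-type", "array"); wa(xd, "encoding-version", "0.2.0")
  rhdf5::H5Dclose(xd)
  for (grp in c("obs", "var")) {
    gid <- rhdf5::H5Gopen(fid, grp)
    wa(gid, "encoding-type", "dataframe")
    wa(gid, "encoding-version", "0.2.0")
    wa(gid, "_index", "_index")
    cols <- if (grp == "obs") {
      c(if (!is.null(data$labels)) "cell_type",
        if (!is.null(data$batch)) "batch")
    } else character(0)
    if (length(cols) > 0) {
      wa(gid, "column-order", cols, asScalar = FALSE)
    } else {
      # anndata writes an empty float array for column-less frames
      rhdf5::h5writeAttribute(numeric(0), gid, "column-order",
                              asScalar = FALSE)
    }
    rhdf5::H5Gclose(gid)
    for (ds in c("_index", if (grp == "obs") cols)) {
      did <- rhdf5::H5Dopen(fid, paste0(grp, "/", ds))
      wa(did, "encoding-type", "string-array")
      wa(did, "encoding-version", "0.2.0")
      rhdf5::H5Dclose(did)
    }
  }
}

#' Write / read a per-cell label table
#'
#' 2-column TSV with header `cell_id<TAB>cell_type`.
#'
#' @param labels Named character vector (names = cell ids) or a
#'   2-column data frame.
#' @param path TSV path.
#' @return `read_labels` returns a named character vector.
#' @export
write_labels <- function(labels, path) {
  if (is.data.frame(labels)) {
    df <- data.frame(cell_id = as.character(labels[[1]]),
                     cell_type = as.character(labels[[2]]))
  } else {
    df <- data.frame(cell_id = names(labels),
                     cell_type = unname(as.character(labels)))
  }
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, colClasses = "character")
  setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Write / read an evaluation report
#'
#' `.json` (structured; lossless round-trip of every field including the
#' confusion matrix) or `.tsv` (flat per-class metric table for
#' spreadsheets).
#'
#' @param report An `evaluation_report`.
#' @param path Output path ending in `.json` or `.tsv`.
#' @return `read_report` returns an `evaluation_report` (JSON only).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  if (length(report$per_class_f1) == 0) stop("empty report", call. = FALSE)
  if (grepl("\\.tsv$", path)) {
    df <- data.frame(metric = c("accuracy", "macro_f1", "median_f1",
                                paste0("f1:", names(report$per_class_f1))),
                     value = c(report$accuracy, report$macro_f1,
                               report$median_f1,
                               unname(report$per_class_f1)))
    data.table::fwrite(df, path, sep = "\t")
  } else {
    obj <- list(protocol = report$protocol,
                accuracy = report$accuracy,
                macro_f1 = report$macro_f1,
                median_f1 = report$median_f1,
                per_class_f1 = as.list(report$per_class_f1),
                confusion = list(labels_true = rownames(report$confusion),
                                 labels_pred = colnames(report$confusion),
                                 counts = unname(apply(report$confusion, 1,
                                                       as.integer,
                                                       simplify = FALSE))),
                n_cells = report$n_cells,
                repeats = report$repeats)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  conf_counts <- obj$confusion$counts
  if (is.list(conf_counts)) conf_counts <- do.call(rbind, conf_counts)
  conf <- matrix(as.integer(t(conf_counts)),
                 nrow = length(obj$confusion$labels_true), byrow = TRUE,
                 dimnames = list(true = obj$confusion$labels_true,
                                 predicted = obj$confusion$labels_pred))
  structure(list(protocol = if (is.null(obj$protocol)) NA_character_ else obj$protocol,
                 accuracy = obj$accuracy, macro_f1 = obj$macro_f1,
                 median_f1 = obj$median_f1,
                 per_class_f1 = unlist(obj$per_class_f1),
                 confusion = conf, n_cells = as.integer(obj$n_cells),
                 repeats = as.integer(obj$repeats)),
            class = "evaluation_report")
}

MODEL_FORMAT <- "cellstack/stacking_model/1"

#' Save / load a fitted stacking model
#'
#' The serialized artifact contains the full model — label codebook,
#' signatures, fitted first-layer learners, meta-learner and the
#' preprocessing settings — so prediction-time processing is entirely
#' self-describing: `load_model(save_model(m))` predicts identically
#' to `m` on any dataset.
#'
#' @param model A fitted `stacking_model`.
#' @param path Output file path.
#' @return `load_model` returns the `stacking_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "stacking_model"))
  saveRDS(list(format = MODEL_FORMAT, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt model file: ", path,
                                           call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT) ||
      !inherits(obj$model, "stacking_model")) {
    stop("corrupt model file or version mismatch: ", path, call. = FALSE)
  }
  obj$model
}

#' Write a prediction table
#'
#' TSV with columns `cell_id`, `predicted_type`, then one probability
#' column per cell type in codebook order.
#'
#' @param pred Result of [predict_types()].
#' @param path Output TSV path.
#' @export
write_predictions <- function(pred, path) {
  df <- data.frame(cell_id = pred$cell_ids,
                   predicted_type = pred$predicted,
                   pred$probabilities, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
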