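#' Project a dataset onto one signature
#'
#' Restricts the columns of `data` to the genes of one signature, in
#' signature order, carrying labels through. Training-side helper: every
#' signature gene must be present (prediction-side gene mismatches are
#' handled by [align_genes()]).
#'
#' @param data An `expression_dataset`.
#' @param f_k Character vector of signature gene ids.
#' @return The projected `expression_dataset`.
#' @export
build_subdataset <- function(data, f_k) {
  stopifnot(inherits(data, "expression_dataset"), length(f_k) >= 1)
  idx <- match(f_k, data$gene_ids)
  if (anyNA(idx)) {
    stop("signature gene(s) absent from dataset: ",
         paste(head(f_k[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  }
  data[, idx]
}

#' Stratified fold assignment
#'
#' Assigns each cell to one of `folds` folds so that every cell type's
#' proportions are preserved up to integer rounding. Deterministic given
#' the seed.
#'
#' @param labels Per-cell type labels.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..folds, one per cell.
#' @export
stratified_folds <- function(labels, folds, seed) {
  labels <- as.character(labels)
  folds <- as.integer(folds)
  stopifnot(folds >= 2)
  assign <- integer(length(labels))
  with_seed(seed, {
    for (ty in sort_c(unique(labels))) {
      idx <- which(labels == ty)
      if (length(idx) < folds) {
        stop("class ", ty, " too small for ", folds,
             "-fold stacking; reduce --stack-folds or drop class",
             call. = FALSE)
      }
      assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Out-of-fold probability transform
#'
#' The first-layer stacking transform: the labeled sub-dataset is split
#' into stratified folds; for each fold the learner is trained on the
#' remaining folds and predicts class probabilities for the held-out
#' cells, so every cell's feature vector comes from a model that never
#' saw it. Columns follow the codebook order.
#'
#' @param sub A labeled `expression_dataset` (a signature sub-dataset).
#' @param learner A [base_learner()] spec.
#' @param folds Number of stacking folds (default 3).
#' @param seed Integer seed driving fold assignment and learner fitting.
#' @param codebook Optional type ordering; defaults to
#'   `label_codebook(sub)`.
#' @param .trace Optional environment; when supplied, the train/held-out
#'   index sets of every fold are appended to `.trace$folds` (used by the
#'   leakage audit).
#' @return n x t matrix of class probabilities, rows in cell order,
#'   each row summing to 1.
#' @export
oof_transform <- function(sub, learner, folds = 3L, seed = 1L,
                          codebook = NULL, .trace = NULL) {
  stopifnot(inherits(sub, "expression_dataset"), !is.null(sub$labels))
  if (is.null(codebook)) codebook <- label_codebook(sub)
  fold_id <- stratified_folds(sub$labels, folds, seed = seed)
  y <- factor(sub$labels, levels = codebook)
  x <- as.matrix(sub$matrix)
  out <- matrix(NA_real_, nrow = nrow(x), ncol = length(codebook),
                dimnames = list(sub$cell_ids, codebook))
  for (f in seq_len(folds)) {
    test_idx <- which(fold_id == f)
    train_idx <- which(fold_id != f)
    if (!is.null(.trace)) {
      .trace$folds <- c(.trace$folds,
                        list(list(train = train_idx, test = test_idx)))
    }
    fit <- fit_learner(learner, x[train_idx, , drop = FALSE], y[train_idx],
                       seed = derive_seed(seed, f))
    out[test_idx, ] <- predict_learner(fit, x[test_idx, , drop = FALSE])
  }
  out
}

#' Fit the two-layer dynamic stacking model
#'
#' End-to-end training on a labeled raw-count dataset:
#' \enumerate{
#'   \item per-cell normalization ([normalize_cells()]);
#'   \item per-type one-vs-rest chi-squared signatures
#'     ([select_signatures()]);
#'   \item for every (cell type, base learner) pair, the out-of-fold
#'     probability transform on that type's signature sub-dataset
#'     ([oof_transform()]); the t-wide blocks are concatenated — outer
#'     loop over types in codebook order, inner loop over learners in
#'     declared order — into an n x (t*L*t) meta-feature matrix (the
#'     classic n x (t x 2t) layout when L = 2);
#'   \item a multinomial L2 logistic-regression meta-learner is fitted on
#'     the meta-features against the true labels;
#'   \item each base learner is refit on its full sub-dataset for use at
#'     prediction time.
#' }
#' The number of first-layer models is t*L, so the ensemble grows
#' dynamically with the number of cell types in the training data.
#'
#' @param data Labeled `expression_dataset` of raw (or already
#'   normalized, see `preprocess`) expression values.
#' @param learners List of [base_learner()] specs (default
#'   [default_learners()]: RBF-SVM + logistic regression).
#' @param k Signature size per cell type (default 300).
#' @param folds Stacking folds for the out-of-fold transform (default 3).
#' @param seed Integer seed; all randomness (fold assignment, learner
#'   fitting) derives from it.
#' @param preprocess A [preprocess_settings()] object applied to the
#'   training data and stored in the model for prediction-time use.
#' @param meta_C Inverse regularization strength of the meta-learner
#'   (default 1).
#' @return A `stacking_model`: list with `codebook`, `signatures`,
#'   `base_models` (one fitted learner per (type, learner) pair),
#'   `meta_model`, `meta_features` (the training meta matrix),
#'   `block_index`, `preprocess`, `learners`, `folds`, `seed`,
#'   `gene_space`.
#' @export
fit_stacking <- function(data, learners = default_learners(), k = 300L,
                         folds = 3L, seed = 1L,
                         preprocess = preprocess_settings(),
                         meta_C = 1) {
  stopifnot(inherits(data, "expression_dataset"))
  if (is.null(data$labels)) stop("training data must be labeled", call. = FALSE)
  learners <- as_learner_list(learners)
  norm <- normalize_cells(data, preprocess)
  codebook <- label_codebook(norm)
  t <- length(codebook)
  L <- length(learners)
  signatures <- select_signatures(norm, k = k)

  n <- n_cells(norm)
  meta <- matrix(NA_real_, nrow = n, ncol = t * L * t)
  block_index <- list()
  base_models <- list()
  col <- 0L
  for (ti in seq_len(t)) {
    ty <- codebook[ti]
    sub <- build_subdataset(norm, signatures$per_type[[ty]])
    for (li in seq_len(L)) {
      lrn <- learners[[li]]
      s <- derive_seed(seed, ti, li)
      block <- oof_transform(sub, lrn, folds = folds, seed = s,
                             codebook = codebook)
      cols <- (col + 1L):(col + t)
      meta[, cols] <- block
      key <- paste(ty, lrn$name, sep = "::")
      block_index[[key]] <- cols
      y <- factor(norm$labels, levels = codebook)
      base_models[[key]] <- fit_learner(lrn, as.matrix(sub$matrix), y,
                                        seed = derive_seed(s, 9999L))
      col <- col + t
    }
  }
  colnames(meta) <- unlist(lapply(names(block_index), function(k2) {
    paste(k2, codebook, sep = "::")
  }))

  y <- factor(norm$labels, levels = codebook)
  lam <- 1 / (n * meta_C)
  meta_model <- quiet_small_class(glmnet::glmnet(
    meta, y, family = "multinomial", alpha = 0,
    lambda = exp(seq(log(lam * 100), log(lam), length.out = 5)),
    standardize = FALSE))

  structure(list(codebook = codebook, signatures = signatures,
                 base_models = base_models, meta_model = meta_model,
                 meta_lambda = lam, meta_features = meta,
                 block_index = block_index, preprocess = preprocess,
                 learners = learners, folds = as.integer(folds),
                 seed = as.integer(seed),
                 gene_space = sort_c(unique(unlist(signatures$per_type,
                                                   use.names = FALSE)))),
            class = "stacking_model")
}

#' @export
print.stacking_model <- function(x, ...) {
  t <- length(x$codebook)
  L <- length(x$learners)
  cat("stacking_model: ", t, " cell types x ", L, " base learners (",
      paste(vapply(x$learners, `[[`, "", "name"), collapse = "+"),
      "), meta width ", t * L * t, "\n", sep = "")
  cat("  types: ", paste(x$codebook, collapse = ", "), "\n", sep = "")
  cat("  signature: k=", x$signatures$k, " genes/type, ",
      length(x$gene_space), " distinct genes; stacking folds=", x$folds,
      "\n", sep = "")
  invisible(x)
}

# Build the t*L*t meta-feature matrix for new (already normalized and
# gene-aligned) data using the refit base learners.
meta_transform <- function(model, aligned) {
  t <- length(model$codebook)
  meta <- matrix(NA_real_, nrow = n_cells(aligned),
                 ncol = t * length(model$learners) * t)
  for (key in names(model$block_index)) {
    ty <- sub("::.*$", "", key)
    sub <- build_subdataset(aligned, model$signatures$per_type[[ty]])
    meta[, model$block_index[[key]]] <-
      predict_learner(model$base_models[[key]], as.matrix(sub$matrix))
  }
  meta
}

#' Predict cell types for new data
#'
#' Normalizes the test data with the model's stored preprocessing
#' settings, aligns its genes onto the model's signature gene space
#' (missing genes zero-filled with a warning), transforms it through the
#' refit first-layer learners into meta-features, and applies the
#' meta-learner. Predicted type is the arg-max of the meta probabilities,
#' ties broken by codebook order. Cells of types absent from training are
#' necessarily assigned some training type: the model cannot discover new
#' cell types.
#'
#' @param model,object A fitted `stacking_model`.
#' @param data An `expression_dataset` (labels not required).
#' @param ... Unused.
#' @return A list with `cell_ids`, `predicted` (character vector) and
#'   `probabilities` (n x t matrix, columns in codebook order).
#' @export
predict_types <- function(model, data) {
  stopifnot(inherits(model, "stacking_model"),
            inherits(data, "expression_dataset"))
  norm <- normalize_cells(data, model$preprocess)
  aligned <- align_genes(model$gene_space, norm, fill = 0)
  meta <- meta_transform(model, aligned)
  p3 <- predict(model$meta_model, meta, s = model$meta_lambda,
                type = "response")
  probs <- p3[, , 1, drop = TRUE]
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(meta))
  colnames(probs) <- model$codebook
  rownames(probs) <- aligned$cell_ids
  pred <- model$codebook[max.col(probs, ties.method = "first")]
  list(cell_ids = aligned$cell_ids, predicted = pred, probabilities = probs)
}

#' @rdname predict_types
#' @export
predict.stacking_model <- function(object, data, ...) {
  predict_types(object, data)
}
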