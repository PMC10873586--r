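#' Classification metrics for cell-type prediction
#'
#' Accuracy (fraction of correctly predicted cells), per-class F1
#' (`2TP / (2TP + FP + FN)`, defined as 0 when the denominator is 0),
#' macro F1 (unweighted mean of per-class F1) and median F1 (median of
#' per-class F1; the mean of the middle two when the class count is
#' even). Per-class F1 is computed over the classes present in the true
#' labels; predicted-only classes still appear in the confusion matrix,
#' which is dimensioned over the sorted union of true and predicted
#' labels.
#'
#' @param true_labels,predicted_labels Equal-length non-empty character
#'   vectors.
#' @param protocol Optional protocol tag (`"intra"`, `"inter"`,
#'   `"cross-batch"`, `"cross-species"`).
#' @return An `evaluation_report`: list with `protocol`, `accuracy`,
#'   `macro_f1`, `median_f1`, `per_class_f1` (named), `confusion`
#'   (integer matrix), `n_cells`, `repeats`.
#' @export
compute_metrics <- function(true_labels, predicted_labels, protocol = NA_character_) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) == 0) stop("empty input", call. = FALSE)
  if (length(true_labels) != length(predicted_labels)) {
    stop("length mismatch between true and predicted labels", call. = FALSE)
  }
  all_lab <- sort_c(unique(c(true_labels, predicted_labels)))
  conf <- table(factor(true_labels, levels = all_lab),
                factor(predicted_labels, levels = all_lab))
  conf <- matrix(as.integer(conf), nrow = length(all_lab),
                 dimnames = list(true = all_lab, predicted = all_lab))
  classes <- sort_c(unique(true_labels))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(true_labels == cl & predicted_labels == cl)
    fp <- sum(true_labels != cl & predicted_labels == cl)
    fn <- sum(true_labels == cl & predicted_labels != cl)
    den <- 2 * tp + fp + fn
    if (den == 0) 0 else 2 * tp / den
  }, numeric(1))
  structure(list(protocol = protocol,
                 accuracy = mean(true_labels == predicted_labels),
                 macro_f1 = mean(f1),
                 median_f1 = stats::median(f1),
                 per_class_f1 = f1,
                 confusion = conf,
                 n_cells = length(true_labels),
                 repeats = 1L),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report",
      if (!is.na(x$protocol)) paste0(" [", x$protocol, "]"), ":\n", sep = "")
  cat(sprintf("  accuracy   %.4f\n  macro F1   %.4f\n  median F1  %.4f\n",
              x$accuracy, x$macro_f1, x$median_f1))
  cat("  n_cells ", x$n_cells, ", repeats ", x$repeats, "\n", sep = "")
  cat("  per-class F1: ",
      paste0(names(x$per_class_f1), "=",
             sprintf("%.3f", x$per_class_f1), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Arithmetic mean of a list of reports (per-class F1 averaged over the
# reports in which the class appears; confusion matrices summed).
average_reports <- function(reports, protocol, repeats) {
  classes <- sort_c(unique(unlist(lapply(reports, function(r) names(r$per_class_f1)))))
  f1 <- vapply(classes, function(cl) {
    v <- vapply(reports, function(r) r$per_class_f1[cl], numeric(1))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  all_lab <- sort_c(unique(unlist(lapply(reports, function(r) rownames(r$confusion)))))
  conf <- matrix(0L, length(all_lab), length(all_lab),
                 dimnames = list(true = all_lab, predicted = all_lab))
  for (r in reports) {
    conf[rownames(r$confusion), colnames(r$confusion)] <-
      conf[rownames(r$confusion), colnames(r$confusion)] + r$confusion
  }
  structure(list(protocol = protocol,
                 accuracy = mean(vapply(reports, `[[`, numeric(1), "accuracy")),
                 macro_f1 = mean(vapply(reports, `[[`, numeric(1), "macro_f1")),
                 median_f1 = mean(vapply(reports, `[[`, numeric(1), "median_f1")),
                 per_class_f1 = f1,
                 confusion = conf,
                 n_cells = sum(vapply(reports, `[[`, numeric(1), "n_cells")),
                 repeats = as.integer(repeats),
                 per_round = reports),
            class = "evaluation_report")
}

#' Stratified k-fold cross-validation of the stacking model
#'
#' Intra-dataset protocol: folds are stratified to preserve each cell
#' type's proportions; for each fold the model is fitted on the
#' remaining folds (feature selection included, so no information leaks
#' from the held-out cells) and evaluated on the held-out fold. Metrics
#' are averaged over folds; per-fold reports are kept in `$per_round`.
#'
#' @param data Labeled `expression_dataset` of raw counts.
#' @param config Named list of arguments passed to [fit_stacking()]
#'   (e.g. `learners`, `k`, `folds`, `preprocess`).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for fold assignment and per-fold model seeds.
#' @return An `evaluation_report` with protocol `"intra"`.
#' @export
stratified_kfold_cv <- function(data, config = list(), folds = 5L, seed = 1L) {
  stopifnot(inherits(data, "expression_dataset"), !is.null(data$labels))
  fold_id <- stratified_folds(data$labels, folds, seed = seed)
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    train <- data[which(fold_id != f), ]
    test <- data[which(fold_id == f), ]
    cfg <- modifyList(list(seed = derive_seed(seed, f)), config)
    model <- do.call(fit_stacking, c(list(train), cfg))
    pred <- predict_types(model, test)
    reports[[f]] <- compute_metrics(test$labels, pred$predicted,
                                    protocol = "intra")
  }
  out <- average_reports(reports, protocol = "intra", repeats = folds)
  out$fold_id <- fold_id
  out
}

#' Train on one dataset (or pool), test on another
#'
#' Inter-dataset / cross-batch / cross-species protocol: the model is
#' fitted on the training data only; the test data is normalized
#' independently and gene-aligned onto the model's signature space.
#' Metrics are computed over the classes present in the test truth;
#' test-only classes are necessarily mispredicted and score F1 = 0.
#'
#' @param train Labeled `expression_dataset`, or a list of them (pooled
#'   over their common gene space with [pool_datasets()]).
#' @param test Labeled `expression_dataset`.
#' @param config Named list of [fit_stacking()] arguments.
#' @param protocol Report tag (default `"inter"`).
#' @param seed Integer model seed (overridden by `config$seed` if set).
#' @return An `evaluation_report`.
#' @export
cross_dataset_eval <- function(train, test, config = list(),
                               protocol = "inter", seed = 1L) {
  if (is.list(train) && !inherits(train, "expression_dataset")) {
    train <- pool_datasets(train)
  }
  stopifnot(inherits(train, "expression_dataset"),
            inherits(test, "expression_dataset"),
            !is.null(train$labels), !is.null(test$labels))
  if (length(intersect(train$gene_ids, test$gene_ids)) == 0) {
    stop("disjoint gene spaces", call. = FALSE)
  }
  cfg <- modifyList(list(seed = seed), config)
  model <- do.call(fit_stacking, c(list(train), cfg))
  pred <- predict_types(model, test)
  compute_metrics(test$labels, pred$predicted, protocol = protocol)
}

#' Class-balanced random down-sampling
#'
#' Every class with more than `target` cells is sampled without
#' replacement down to exactly `target`; smaller classes are kept whole.
#' The relative order of the retained cells is preserved. This is the
#' random under-sampling strategy used to balance a heavily skewed
#' training set before cross-species prediction.
#'
#' @param data Labeled `expression_dataset`.
#' @param target Per-class target size (>= 1).
#' @param seed Integer seed.
#' @return The down-sampled `expression_dataset`.
#' @export
downsample_per_class <- function(data, target, seed = 1L) {
  stopifnot(inherits(data, "expression_dataset"), !is.null(data$labels))
  if (target < 1) stop("target must be >= 1", call. = FALSE)
  keep <- with_seed(seed, {
    unlist(lapply(sort_c(unique(data$labels)), function(ty) {
      idx <- which(data$labels == ty)
      if (length(idx) > target) sample(idx, target) else idx
    }), use.names = FALSE)
  })
  data[sort(keep), ]
}

#' Repeated down-sampled cross-dataset evaluation
#'
#' Runs `repeats` independent rounds of class-balanced down-sampling of
#' the training data (round r uses seed `seed + r`), fits and evaluates
#' the model on each round, and reports the arithmetic mean of the
#' metrics; per-round reports are kept in `$per_round`.
#'
#' @inheritParams cross_dataset_eval
#' @param target Per-class down-sampling target.
#' @param repeats Number of rounds (default 5).
#' @param seed Integer base seed.
#' @return An `evaluation_report` with `repeats` set.
#' @export
repeated_downsample_eval <- function(train, test, target, repeats = 5L,
                                     config = list(),
                                     protocol = "cross-species", seed = 1L) {
  stopifnot(repeats >= 1)
  reports <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    # round seeds drive the down-sampling only; the model seed stays at
    # `seed` so rounds differ exactly through the sampled training set
    ds <- downsample_per_class(train, target, seed = as.integer(seed) + r)
    reports[[r]] <- cross_dataset_eval(
      ds, test, config = config, protocol = protocol, seed = seed)
  }
  average_reports(reports, protocol = protocol, repeats = repeats)
}
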