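test_that("sub-dataset projection restricts columns in signature order", {
  d <- tiny_dataset()
  f <- c("g05", "g01", "g09")
  sub <- build_subdataset(d, f)
  expect_equal(sub$gene_ids, f)
  expect_equal(as.matrix(sub$matrix),
               as.matrix(d$matrix)[, c(5, 1, 9)], ignore_attr = TRUE)
  expect_equal(sub$labels, d$labels)
  expect_equal(build_subdataset(d, d$gene_ids)$matrix, d$matrix)
  expect_error(build_subdataset(d, c("g01", "nope")), "absent")
})

test_that("stratified folds cover all cells, are disjoint, and preserve ratios", {
  labels <- rep(c("A", "B"), c(60, 40))
  fid <- stratified_folds(labels, 5, seed = 1)
  expect_equal(sort(unique(fid)), 1:5)
  for (f in 1:5) {
    expect_equal(sum(fid == f & labels == "A"), 12)
    expect_equal(sum(fid == f & labels == "B"), 8)
  }
  expect_identical(fid, stratified_folds(labels, 5, seed = 1))
  expect_error(stratified_folds(c("A", "A", "B"), 2, seed = 1),
               "too small for 2-fold")
})

test_that("out-of-fold transform is leakage-free and probability-valid", {
  d <- tiny_dataset(n_per = 9)
  norm <- normalize_cells(d)
  sub <- build_subdataset(norm, select_signatures(norm, 6)$per_type[["A"]])
  trace <- new.env()
  trace$folds <- list()
  block <- oof_transform(sub, base_learner("lr"), folds = 3, seed = 4,
                         .trace = trace)
  expect_equal(dim(block), c(27L, 3L))
  expect_equal(colnames(block), c("A", "B", "C"))
  expect_true(all(block >= 0 & block <= 1))
  expect_equal(unname(rowSums(block)), rep(1, 27), tolerance = 1e-6)
  # every cell predicted by a model that never saw it; folds cover all cells
  covered <- integer(0)
  for (fd in trace$folds) {
    expect_length(intersect(fd$train, fd$test), 0)
    covered <- c(covered, fd$test)
  }
  expect_setequal(covered, seq_len(27))
  expect_equal(anyDuplicated(covered), 0L)
})

test_that("held-out probability mass lands on the true class when separable", {
  d <- simulate_dataset(simulation_config(cells_per_type = 60, seed = 9))
  norm <- normalize_cells(d)
  sig <- select_signatures(norm, 20)
  sub <- build_subdataset(norm, sig$per_type[["type01"]])
  for (lrn in list(base_learner("lr"), base_learner("svm"))) {
    block <- oof_transform(sub, lrn, folds = 3, seed = 2)
    p_true <- block[cbind(seq_len(nrow(block)),
                          match(d$labels, colnames(block)))]
    expect_gte(mean(p_true > 0.9), 0.95)
  }
})

test_that("meta-feature geometry follows t * L * t and base model count t * L", {
  d <- tiny_dataset(n_per = 8)
  m2 <- fit_stacking(d, learners = default_learners(), k = 6, seed = 1)
  expect_equal(ncol(m2$meta_features), 3 * 2 * 3)
  expect_length(m2$base_models, 6)
  m4 <- fit_stacking(d, learners = list(base_learner("lr"),
                                        base_learner("svm"),
                                        base_learner("rf", params = list(num_trees = 50)),
                                        base_learner("gbc", params = list(nrounds = 20))),
                     k = 6, seed = 1)
  expect_equal(ncol(m4$meta_features), 3 * 4 * 3)
  expect_length(m4$base_models, 12)
  # every t-wide block row is a probability vector
  for (cols in m4$block_index) {
    expect_equal(unname(rowSums(m4$meta_features[, cols])),
                 rep(1, n_cells(d)), tolerance = 1e-6)
  }
})

test_that("prediction contract: shapes, ties, permutation equivariance", {
  d <- tiny_dataset(n_per = 8)
  model <- fit_stacking(d, learners = list(base_learner("lr")), k = 6, seed = 2)
  p <- predict_types(model, d)
  expect_equal(dim(p$probabilities), c(24L, 3L))
  expect_equal(unname(rowSums(p$probabilities)), rep(1, 24),
               tolerance = 1e-6)
  expect_true(all(p$predicted %in% model$codebook))
  perm <- rev(seq_len(24))
  pp <- predict_types(model, d[perm, ])
  expect_equal(pp$predicted, p$predicted[perm])
  expect_equal(unname(pp$probabilities), unname(p$probabilities[perm, ]))
})

test_that("identical seeds give identical models and predictions", {
  d <- simulate_dataset(simulation_config(cells_per_type = 40, n_genes = 300,
                                          seed = 3))
  m1 <- fit_stacking(d, k = 20, seed = 77)
  m2 <- fit_stacking(d, k = 20, seed = 77)
  expect_identical(m1$meta_features, m2$meta_features)
  p1 <- predict_types(m1, d)
  p2 <- predict_types(m2, d)
  expect_identical(p1$probabilities, p2$probabilities)
  expect_identical(p1$predicted, p2$predicted)
})

test_that("stacking does not degrade far below its single base learner", {
  d <- simulate_dataset(simulation_config(cells_per_type = 50, n_genes = 400,
                                          seed = 13))
  cfg_single <- list(learners = list(base_learner("lr")), k = 20)
  stacked <- stratified_kfold_cv(d, cfg_single, folds = 3, seed = 5)
  # base learner alone, same folds: fit lr on the same signatures directly
  fid <- stacked$fold_id
  accs <- vapply(1:3, function(f) {
    train <- d[which(fid != f), ]
    test <- d[which(fid == f), ]
    norm <- normalize_cells(train)
    sig <- select_signatures(norm, 20)
    genes <- sort(unique(unlist(sig$per_type)), method = "radix")
    y <- factor(norm$labels)
    fit <- cellstack:::fit_learner(base_learner("lr"),
                                   as.matrix(build_subdataset(norm, genes)$matrix),
                                   y, seed = 1)
    tn <- align_genes(genes, normalize_cells(test))
    pr <- cellstack:::predict_learner(fit, as.matrix(tn$matrix))
    mean(levels(y)[max.col(pr, ties.method = "first")] == test$labels)
  }, numeric(1))
  expect_gte(stacked$accuracy, mean(accs) - 0.02)
})

test_that("a model survives save/load with bit-identical predictions", {
  d <- tiny_dataset(n_per = 8)
  model <- fit_stacking(d, k = 6, seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  p1 <- predict_types(model, d)
  p2 <- predict_types(back, d)
  expect_identical(p1$predicted, p2$predicted)
  expect_identical(p1$probabilities, p2$probabilities)
  # truncated file is reported as corrupt
  raw <- readBin(path, "raw", file.size(path))
  bad <- withr::local_tempfile(fileext = ".rds")
  writeBin(raw[1:50], bad)
  expect_error(load_model(bad), "corrupt model file")
  # wrong payload is a version/format error
  bad2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "other/2", model = 1), bad2)
  expect_error(load_model(bad2), "corrupt model file|version")
})

test_that("prediction copes with signature genes missing from the test data", {
  d <- simulate_dataset(simulation_config(cells_per_type = 40, n_genes = 300,
                                          seed = 21))
  model <- fit_stacking(d, learners = list(base_learner("lr")), k = 15,
                        seed = 1)
  drop <- head(intersect(model$gene_space, d$marker_map[["type01"]]), 3)
  keep <- setdiff(d$gene_ids, drop)
  expect_warning(p <- predict_types(model, d[, keep]), "imputed")
  expect_equal(unname(rowSums(p$probabilities)), rep(1, n_cells(d)),
               tolerance = 1e-6)
  others <- d$labels != "type01"
  expect_gte(mean(p$predicted[others] == d$labels[others]), 0.9)
})
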