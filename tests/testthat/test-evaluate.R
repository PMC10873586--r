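test_that("metrics match hand-computed examples", {
  r <- compute_metrics(c("A", "A", "B", "B"), c("A", "A", "B", "B"))
  expect_equal(r$accuracy, 1)
  expect_equal(r$macro_f1, 1)
  expect_equal(r$median_f1, 1)

  r2 <- compute_metrics(c("A", "A", "B", "B"), c("A", "A", "A", "A"))
  expect_equal(r2$accuracy, 0.5)
  expect_equal(unname(r2$per_class_f1["A"]), 2 / 3)
  expect_equal(unname(r2$per_class_f1["B"]), 0)
  expect_equal(r2$macro_f1, 1 / 3)
  expect_equal(r2$median_f1, 1 / 3)

  # even class count: median is the mean of the middle two
  r3 <- compute_metrics(c("A", "B", "C", "D"), c("A", "B", "C", "A"))
  expect_equal(r3$median_f1, mean(sort(r3$per_class_f1)[2:3]))

  expect_error(compute_metrics(character(0), character(0)), "empty")
  expect_error(compute_metrics(c("A", "B"), "A"), "length mismatch")
})

test_that("metrics agree with the confusion-matrix oracle on random cases", {
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(2:50, 1)
    t <- sample(2:6, 1)
    classes <- LETTERS[seq_len(t)]
    true <- sample(classes, n, replace = TRUE)
    if (length(unique(true)) < 2) true[1:2] <- classes[1:2]
    pred <- sample(classes, n, replace = TRUE)
    r <- compute_metrics(true, pred)
    o <- oracle_metrics(true, pred)
    expect_equal(r$accuracy, o$accuracy, tolerance = 1e-12)
    expect_equal(r$macro_f1, o$macro_f1, tolerance = 1e-12)
    expect_equal(r$median_f1, o$median_f1, tolerance = 1e-12)
    expect_equal(r$per_class_f1, o$per_class_f1, tolerance = 1e-12)
    expect_equal(sum(r$confusion), r$n_cells)
  }
})

test_that("the constant majority predictor scores exactly the majority frequency", {
  set.seed(7)
  true <- sample(c("A", "B", "C"), 60, replace = TRUE, prob = c(.5, .3, .2))
  maj <- names(which.max(table(true)))
  r <- compute_metrics(true, rep(maj, 60))
  expect_equal(r$accuracy, mean(true == maj))
})

test_that("stratified CV preserves ratios, is seeded, and averages fold reports", {
  d <- simulate_dataset(simulation_config(n_types = 2,
                                          cells_per_type = c(60, 40),
                                          n_genes = 200, seed = 15))
  r1 <- stratified_kfold_cv(d, fast_config(k = 10), folds = 5, seed = 42)
  for (f in 1:5) {
    expect_equal(sum(r1$fold_id == f & d$labels == "type01"), 12)
    expect_equal(sum(r1$fold_id == f & d$labels == "type02"), 8)
  }
  expect_length(r1$per_round, 5)
  expect_equal(r1$accuracy,
               mean(vapply(r1$per_round, `[[`, numeric(1), "accuracy")))
  expect_equal(sum(r1$confusion), n_cells(d))
  r2 <- stratified_kfold_cv(d, fast_config(k = 10), folds = 5, seed = 42)
  expect_identical(r1$fold_id, r2$fold_id)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$per_class_f1, r2$per_class_f1)
})

test_that("cross-dataset evaluation scores test-only classes as F1 zero", {
  pair <- simulate_pair(simulation_config(cells_per_type = 40, n_genes = 300,
                                          seed = 8),
                        mode = "label-subset")
  extra <- setdiff(unique(pair$test$labels), unique(pair$train$labels))
  r <- cross_dataset_eval(pair$train, pair$test, fast_config(k = 10),
                          protocol = "cross-species")
  expect_true(extra %in% names(r$per_class_f1))
  expect_equal(unname(r$per_class_f1[extra]), 0)
  expect_true(extra %in% rownames(r$confusion))
})

test_that("down-sampling hits the per-class target and keeps small classes whole", {
  d <- simulate_dataset(simulation_config(n_types = 3,
                                          cells_per_type = c(120, 30, 80),
                                          n_genes = 20, markers_per_type = 2,
                                          seed = 10))
  ds <- downsample_per_class(d, 30, seed = 1)
  expect_equal(unname(c(table(ds$labels))), c(30, 30, 30))
  # cells kept in original relative order
  expect_identical(ds$cell_ids, d$cell_ids[d$cell_ids %in% ds$cell_ids])
  # no-op when target exceeds every class
  expect_equal(n_cells(downsample_per_class(d, 500, seed = 1)), n_cells(d))
  # deterministic in the seed
  expect_identical(downsample_per_class(d, 30, seed = 3)$cell_ids,
                   downsample_per_class(d, 30, seed = 3)$cell_ids)
  expect_error(downsample_per_class(d, 0), ">= 1")
})

test_that("repeated down-sampled evaluation reduces and averages correctly", {
  pair <- simulate_pair(simulation_config(cells_per_type = 40, n_genes = 200,
                                          seed = 12),
                        mode = "batch-shift")
  # repeats = 1 equals a single downsample + cross_dataset_eval round
  r1 <- repeated_downsample_eval(pair$train, pair$test, target = 30,
                                 repeats = 1, config = fast_config(k = 10),
                                 seed = 5)
  ds <- downsample_per_class(pair$train, 30, seed = 6)
  r0 <- cross_dataset_eval(ds, pair$test, fast_config(k = 10),
                           protocol = "cross-species", seed = 5)
  expect_equal(r1$accuracy, r0$accuracy)
  expect_equal(r1$per_class_f1, r0$per_class_f1)
  # degenerate target: every round sees the identical training set, so
  # a deterministic learner gives zero variance across rounds
  r3 <- repeated_downsample_eval(pair$train, pair$test, target = 1000,
                                 repeats = 3, config = fast_config(k = 10),
                                 seed = 5)
  accs <- vapply(r3$per_round, `[[`, numeric(1), "accuracy")
  expect_equal(max(accs) - min(accs), 0)
  expect_equal(r3$repeats, 3L)
})
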