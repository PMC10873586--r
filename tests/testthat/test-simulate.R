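test_that("the generator is reproducible and validates its configuration", {
  cfg <- simulation_config(n_types = 2, cells_per_type = c(10, 15),
                           n_genes = 30, markers_per_type = 3, seed = 4)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.matrix(d1$matrix), as.matrix(d2$matrix))
  expect_equal(unname(c(table(d1$labels))), c(10, 15))
  expect_length(unlist(d1$marker_map), 6)
  expect_error(simulation_config(n_types = 5, n_genes = 10,
                                 markers_per_type = 3),
               "markers_per_type")
})

test_that("counts follow the negative-binomial mean/variance at 10k draws", {
  cfg <- simulation_config(n_types = 2, cells_per_type = 10, n_genes = 500,
                           markers_per_type = 0, base_mean = 5,
                           dispersion = 0.3, seed = 99)
  d <- simulate_dataset(cfg)
  x <- as.vector(as.matrix(d$matrix))  # 10k iid baseline draws
  mu <- 5; disp <- 0.3
  expect_equal(mean(x), mu, tolerance = 0.05)
  expect_equal(var(x), mu + disp * mu^2, tolerance = 0.15)
})

test_that("markers are up-shifted by about exp(lfc) in their own type", {
  d <- simulate_dataset(simulation_config(cells_per_type = 300, seed = 17))
  for (ty in names(d$marker_map)) {
    own <- which(d$labels == ty)
    other <- which(d$labels != ty)
    mk <- match(d$marker_map[[ty]], d$gene_ids)
    ratio <- mean(as.matrix(d$matrix)[own, mk]) /
      mean(as.matrix(d$matrix)[other, mk])
    expect_equal(ratio, exp(2), tolerance = 0.1)
  }
})

test_that("zero batch effect leaves per-gene batch means statistically equal", {
  d <- simulate_dataset(simulation_config(cells_per_type = 200, n_genes = 400,
                                          markers_per_type = 0,
                                          batch_effect_sd = 0, n_batches = 2,
                                          seed = 23))
  b1 <- which(d$batch == "batch1")
  b2 <- which(d$batch == "batch2")
  m <- as.matrix(d$matrix)
  z <- vapply(seq_len(ncol(m)), function(j) {
    se <- sqrt(var(m[b1, j]) / length(b1) + var(m[b2, j]) / length(b2))
    abs(mean(m[b1, j]) - mean(m[b2, j])) / se
  }, numeric(1))
  expect_gte(mean(z < 4), 0.99)
})

test_that("with zero marker effect planted markers show no rank enrichment", {
  d <- simulate_dataset(simulation_config(cells_per_type = 100,
                                          n_genes = 1000,
                                          markers_per_type = 30,
                                          log_fold_change = 0, seed = 31))
  norm <- normalize_cells(d)
  y <- binarize_labels(norm$labels, "type01")
  s <- chi2_scores(norm$matrix, y)
  ranks <- rank(-s, ties.method = "average")
  mk <- match(d$marker_map[["type01"]], d$gene_ids)
  ks <- suppressWarnings(ks.test(ranks[mk] / length(s), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulate_pair produces the two fixture modes deterministically", {
  cfg <- simulation_config(cells_per_type = 20, n_genes = 100, seed = 3)
  p1 <- simulate_pair(cfg, "batch-shift")
  p2 <- simulate_pair(cfg, "batch-shift")
  expect_identical(as.matrix(p1$train$matrix), as.matrix(p2$train$matrix))
  expect_identical(as.matrix(p1$test$matrix), as.matrix(p2$test$matrix))
  expect_setequal(unique(p1$train$labels), unique(p1$test$labels))
  expect_length(intersect(p1$train$cell_ids, p1$test$cell_ids), 0)

  ls <- simulate_pair(cfg, "label-subset")
  expect_length(setdiff(unique(ls$test$labels), unique(ls$train$labels)), 1)
  expect_equal(ls$train$gene_ids, ls$test$gene_ids)
})
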