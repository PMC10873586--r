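# Independent brute-force oracles, deliberately written from first
# principles (scalar loops, no shared code with the implementation).

# Per-gene chi-squared over class-wise value sums, one gene at a time.
oracle_chi2 <- function(m, y) {
  m <- as.matrix(m)
  out <- numeric(ncol(m))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  n <- n1 + n0
  for (j in seq_len(ncol(m))) {
    o1 <- 0; o0 <- 0
    for (i in seq_len(nrow(m))) {
      if (y[i] == 1) o1 <- o1 + m[i, j] else o0 <- o0 + m[i, j]
    }
    tot <- o1 + o0
    if (tot == 0) { out[j] <- 0; next }
    e1 <- tot * n1 / n
    e0 <- tot * n0 / n
    out[j] <- (o1 - e1)^2 / e1 + (o0 - e0)^2 / e0
  }
  out
}

# Accuracy / per-class F1 / macro / median from an explicit confusion
# matrix built by pair counting.
oracle_metrics <- function(true, pred) {
  classes <- sort(unique(true), method = "radix")
  f1 <- numeric(length(classes))
  names(f1) <- classes
  for (cl in classes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(true)) {
      if (pred[i] == cl && true[i] == cl) tp <- tp + 1
      if (pred[i] == cl && true[i] != cl) fp <- fp + 1
      if (pred[i] != cl && true[i] == cl) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[cl] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  list(accuracy = sum(true == pred) / length(true),
       macro_f1 = mean(f1),
       median_f1 = median(f1),
       per_class_f1 = f1)
}

# Tiny deterministic labeled dataset for plumbing tests.
tiny_dataset <- function(n_per = 6, n_genes = 12, seed = 11) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    labels <- rep(c("A", "B", "C"), each = n_per)
    n <- length(labels)
    m <- matrix(rpois(n * n_genes, 5), nrow = n)
    # plant obvious structure: gene block per type
    for (k in 1:3) {
      rows <- which(labels == c("A", "B", "C")[k])
      cols <- ((k - 1) * 2 + 1):(k * 2)
      m[rows, cols] <- m[rows, cols] + 40
    }
    expression_dataset(m, gene_ids = sprintf("g%02d", seq_len(n_genes)),
                       cell_ids = sprintf("c%02d", seq_len(n)),
                       labels = labels)
  })
}

fast_config <- function(k = 15, folds = 3) {
  list(learners = list(base_learner("lr")), k = k, folds = folds)
}
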