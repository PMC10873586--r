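#' Simulation configuration
#'
#' Parameters of the synthetic scRNA-seq count generator. Counts are
#' negative-binomial (the standard over-dispersed count model for
#' scRNA-seq; `size = 1/dispersion`), with each cell type's planted
#' marker genes up-shifted in mean by a factor `exp(log_fold_change)`
#' and, when `n_batches > 1`, a per-batch per-gene multiplicative
#' log-normal factor with standard deviation `batch_effect_sd` on the
#' log scale. Defaults describe a well-separated three-type reference of
#' 200 cells per type — 1000 genes, 10 markers per type, log-fold-change
#' 2, base mean 5, dispersion 0.3, no batch structure.
#'
#' @param n_types Number of cell types (>= 2).
#' @param cells_per_type Integer vector of per-type cell counts (recycled
#'   to `n_types`; unequal values create class imbalance).
#' @param n_genes Number of genes; must be >= `n_types * markers_per_type`.
#' @param markers_per_type Planted marker genes per type (disjoint across
#'   types).
#' @param log_fold_change Marker mean up-shift on the natural-log scale.
#' @param base_mean Baseline negative-binomial mean per gene.
#' @param dispersion Negative-binomial over-dispersion (> 0);
#'   `variance = mu + dispersion * mu^2`.
#' @param batch_effect_sd SD of the per-batch per-gene log-normal scaling
#'   (0 = no batch effect).
#' @param n_batches Number of batches (>= 1); cells are assigned to
#'   batches round-robin within each type, so every batch contains every
#'   type.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_types = 3L, cells_per_type = 200L,
                              n_genes = 1000L, markers_per_type = 10L,
                              log_fold_change = 2, base_mean = 5,
                              dispersion = 0.3, batch_effect_sd = 0,
                              n_batches = 1L, seed = 1L) {
  n_types <- as.integer(n_types)
  cells_per_type <- rep_len(as.integer(cells_per_type), n_types)
  stopifnot(n_types >= 2, all(cells_per_type >= 1), n_genes >= 1,
            markers_per_type >= 0,
            n_types * markers_per_type <= n_genes,
            log_fold_change >= 0, base_mean > 0, dispersion > 0,
            batch_effect_sd >= 0, n_batches >= 1)
  structure(list(n_types = n_types, cells_per_type = cells_per_type,
                 n_genes = as.integer(n_genes),
                 markers_per_type = as.integer(markers_per_type),
                 log_fold_change = log_fold_change, base_mean = base_mean,
                 dispersion = dispersion, batch_effect_sd = batch_effect_sd,
                 n_batches = as.integer(n_batches), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a labeled scRNA-seq dataset with planted markers
#'
#' Draws a cells x genes count matrix from the negative-binomial model
#' described in [simulation_config()]. Marker genes of type k occupy a
#' disjoint block of the gene space; a cell of type k has those genes'
#' means multiplied by `exp(log_fold_change)`. The planted marker map is
#' returned as the `marker_map` element for ground-truth checks.
#'
#' @param config A [simulation_config()].
#' @return An `expression_dataset` (dense integer counts) with `labels`,
#'   `batch` (when `n_batches > 1`) and an extra element `marker_map`
#'   (list: type -> marker gene ids).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  c0 <- config
  types <- sprintf("type%02d", seq_len(c0$n_types))
  gene_ids <- sprintf("g%05d", seq_len(c0$n_genes))
  n <- sum(c0$cells_per_type)
  cell_ids <- sprintf("cell%06d", seq_len(n))
  labels <- rep(types, times = c0$cells_per_type)
  batch <- unlist(lapply(c0$cells_per_type, function(nc) {
    sprintf("batch%d", rep_len(seq_len(c0$n_batches), nc))
  }), use.names = FALSE)

  marker_map <- setNames(lapply(seq_len(c0$n_types), function(k) {
    if (c0$markers_per_type == 0) return(character(0))
    gene_ids[((k - 1) * c0$markers_per_type + 1):(k * c0$markers_per_type)]
  }), types)

  counts <- with_seed(c0$seed, {
    batch_factor <- matrix(exp(rnorm(c0$n_batches * c0$n_genes,
                                     sd = c0$batch_effect_sd)),
                           nrow = c0$n_batches)
    m <- matrix(0, nrow = n, ncol = c0$n_genes)
    for (i in seq_len(n)) {
      mu <- rep(c0$base_mean, c0$n_genes)
      mk <- marker_map[[labels[i]]]
      if (length(mk)) mu[match(mk, gene_ids)] <- mu[match(mk, gene_ids)] *
          exp(c0$log_fold_change)
      mu <- mu * batch_factor[as.integer(sub("batch", "", batch[i])), ]
      m[i, ] <- rnbinom(c0$n_genes, mu = mu, size = 1 / c0$dispersion)
    }
    m
  })

  out <- expression_dataset(counts, gene_ids = gene_ids, cell_ids = cell_ids,
                            labels = labels,
                            batch = if (c0$n_batches > 1) batch else NULL)
  out$marker_map <- marker_map
  out
}

#' Simulate a matched train/test dataset pair
#'
#' Two fixture modes for the cross-dataset protocols:
#' \describe{
#'   \item{`"batch-shift"`}{One dataset is generated with two batches;
#'     the first batch becomes the training set and the second the test
#'     set. With `batch_effect_sd = 0` the pair is exchangeable.}
#'   \item{`"label-subset"`}{The test set carries one extra cell type
#'     absent from training (the cross-species situation where some
#'     types exist only in the target species); train and test are
#'     independent draws over the same gene space.}
#' }
#'
#' @param config A [simulation_config()].
#' @param mode `"batch-shift"` or `"label-subset"`.
#' @return List with elements `train` and `test`
#'   (`expression_dataset`s, each with `marker_map`).
#' @export
simulate_pair <- function(config = simulation_config(),
                          mode = c("batch-shift", "label-subset")) {
  mode <- match.arg(mode)
  if (mode == "batch-shift") {
    cfg <- config
    cfg$n_batches <- 2L
    d <- simulate_dataset(cfg)
    train <- d[which(d$batch == "batch1"), ]
    test <- d[which(d$batch == "batch2"), ]
    train$marker_map <- d$marker_map
    test$marker_map <- d$marker_map
    list(train = train, test = test)
  } else {
    cfg <- config
    cfg$n_types <- config$n_types + 1L
    cfg$cells_per_type <- rep_len(config$cells_per_type, cfg$n_types)
    stopifnot(cfg$n_types * cfg$markers_per_type <= cfg$n_genes)
    full_train <- simulate_dataset(cfg)
    cfg2 <- cfg
    cfg2$seed <- derive_seed(cfg$seed, 2L)
    test <- simulate_dataset(cfg2)
    held_out <- sprintf("type%02d", cfg$n_types)
    train <- full_train[which(full_train$labels != held_out), ]
    train$marker_map <- full_train$marker_map[
      setdiff(names(full_train$marker_map), held_out)]
    test$cell_ids <- paste0("t_", test$cell_ids)
    rownames(test$matrix) <- test$cell_ids
    list(train = train, test = test)
  }
}
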