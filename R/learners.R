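#' Specify a probabilistic base learner
#'
#' Base learners transform a signature sub-dataset into class-probability
#' features; each must return, per cell, a length-t non-negative vector
#' summing to 1. Available kinds:
#' \describe{
#'   \item{`"svm"`}{RBF-kernel support-vector machine with Platt-style
#'     probability calibration via pairwise coupling (\pkg{e1071}).
#'     Defaults: `cost = 1`, `gamma = 1 / (m * var(x))`.}
#'   \item{`"lr"`}{Multinomial L2 (ridge) logistic regression
#'     (\pkg{glmnet}), penalty strength `C = 1` mapped to
#'     `lambda = 1 / (n * C)`.}
#'   \item{`"rf"`}{Probability random forest (\pkg{ranger}), 500 trees.}
#'   \item{`"gbc"`}{Gradient boosting (\pkg{xgboost}), 100 rounds,
#'     `eta = 0.1`, `max_depth = 3`.}
#'   \item{`"mlp"`}{Single-hidden-layer perceptron with softmax output
#'     (\pkg{nnet}), 50 hidden units.}
#' }
#'
#' @param kind One of `"svm"`, `"lr"`, `"rf"`, `"gbc"`, `"mlp"`.
#' @param name Display name; defaults to `kind`.
#' @param params Named list of hyperparameter overrides (e.g.
#'   `list(cost = 10)` for svm, `list(C = 0.5)` for lr,
#'   `list(num_trees = 200)` for rf, `list(nrounds = 50)` for gbc,
#'   `list(size = 20)` for mlp).
#' @param seed Optional learner-level seed; when NULL the fitting
#'   routines derive one from the model seed.
#' @return A `base_learner` specification.
#' @export
base_learner <- function(kind = c("svm", "lr", "rf", "gbc", "mlp"),
                         name = NULL, params = list(), seed = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, name = if (is.null(name)) kind else name,
                 params = params, seed = seed),
            class = "base_learner")
}

#' Default base-learner set
#'
#' RBF-SVM followed by logistic regression: the default first-layer pair.
#' @return List of two `base_learner` specs.
#' @export
default_learners <- function() list(base_learner("svm"), base_learner("lr"))

# glmnet warns on classes with < 8 observations; routine for small
# stacking folds, so muffled here (any other warning passes through).
quiet_small_class <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("dangerous ground|fewer than 8", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

as_learner_list <- function(learners) {
  if (inherits(learners, "base_learner")) learners <- list(learners)
  if (is.character(learners)) learners <- lapply(learners, base_learner)
  stopifnot(all(vapply(learners, inherits, logical(1), "base_learner")))
  if (length(learners) == 0) stop("need at least one base learner", call. = FALSE)
  learners
}

# Fit one base learner on a dense x (cells x genes) against a factor y
# whose levels are the full codebook. Deterministic given `seed`.
fit_learner <- function(spec, x, y, seed) {
  stopifnot(is.factor(y), nrow(x) == length(y))
  x <- as.matrix(x)
  if (!is.null(spec$seed)) seed <- spec$seed
  p <- spec$params
  fit <- switch(spec$kind,
    lr = {
      C <- if (!is.null(p$C)) p$C else 1
      lam <- 1 / (nrow(x) * C)
      xx <- if (ncol(x) < 2) cbind(x, .pad = 0) else x
      quiet_small_class(
        glmnet::glmnet(xx, y, family = "multinomial", alpha = 0,
                       lambda = exp(seq(log(lam * 100), log(lam),
                                        length.out = 5)),
                       standardize = FALSE))
    },
    svm = {
      g <- if (!is.null(p$gamma)) p$gamma else {
        v <- stats::var(as.vector(x))
        if (is.na(v) || v == 0) 1 / ncol(x) else 1 / (ncol(x) * v)
      }
      with_seed(seed,
        e1071::svm(x, y, kernel = "radial",
                   cost = if (!is.null(p$cost)) p$cost else 1,
                   gamma = g, probability = TRUE, scale = FALSE))
    },
    rf = ranger::ranger(
      x = x, y = y, probability = TRUE,
      num.trees = if (!is.null(p$num_trees)) p$num_trees else 500L,
      seed = seed, num.threads = 1L),
    gbc = {
      d <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = nlevels(y),
                      eta = if (!is.null(p$eta)) p$eta else 0.1,
                      max_depth = if (!is.null(p$max_depth)) p$max_depth else 3L,
                      nthread = 1L, seed = seed),
        data = d,
        nrounds = if (!is.null(p$nrounds)) p$nrounds else 100L,
        verbose = 0)
    },
    mlp = with_seed(seed,
      nnet::nnet(x, nnet::class.ind(y),
                 size = if (!is.null(p$size)) p$size else 50L,
                 decay = if (!is.null(p$decay)) p$decay else 1e-4,
                 softmax = TRUE, maxit = 200L, MaxNWts = 1e6,
                 trace = FALSE))
  )
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 C = if (spec$kind == "lr") {
                   if (!is.null(p$C)) p$C else 1
                 } else NULL,
                 lambda = if (spec$kind == "lr") {
                   1 / (nrow(x) * (if (!is.null(p$C)) p$C else 1))
                 } else NULL),
            class = "fitted_learner")
}

# Class-probability prediction; columns ordered by the fitted codebook
# (zero-filled for any level the learner did not see, which cannot occur
# under stratified folds but keeps the contract airtight).
predict_learner <- function(object, x) {
  stopifnot(inherits(object, "fitted_learner"))
  x <- as.matrix(x)
  lev <- object$levels
  p <- switch(object$spec$kind,
    lr = {
      xx <- if (ncol(x) < 2) cbind(x, .pad = 0) else x
      drop3 <- predict(object$fit, xx, s = object$lambda, type = "response")
      drop3[, , 1, drop = TRUE]
    },
    svm = {
      pr <- predict(object$fit, x, probability = TRUE)
      attr(pr, "probabilities")
    },
    rf = predict(object$fit, data = x, num.threads = 1L)$predictions,
    gbc = {
      m <- predict(object$fit, xgboost::xgb.DMatrix(x))
      colnames(m) <- lev
      m
    },
    mlp = {
      m <- predict(object$fit, x)
      colnames(m) <- colnames(object$fit$fitted.values)
      m
    })
  if (is.null(dim(p))) p <- matrix(p, nrow = nrow(x), dimnames = list(NULL, lev))
  out <- matrix(0, nrow = nrow(x), ncol = length(lev),
                dimnames = list(rownames(x), lev))
  common <- intersect(colnames(p), lev)
  out[, common] <- as.matrix(p[, common, drop = FALSE])
  rs <- rowSums(out)
  rs[rs == 0] <- 1
  out / rs
}
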