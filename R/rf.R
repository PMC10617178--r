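#' Random forest configuration
#'
#' @param n_trees number of trees (1000 by default for desk-scale runs;
#'   50000 mirrors the full-size analysis)
#' @param subsample_frac fraction of each class used to train each tree;
#'   the held-out remainder is that tree's test set
#' @param mtry candidate features per split (default floor(sqrt(m)))
#' @param k_folds folds for the cross-validation scheme
#' @param seed RNG seed
#' @param replace draw the per-tree training sample with replacement
#'   (bootstrap) instead of the default subsampling without replacement
#' @return object of class \code{rf_config}
#' @export
rf_config <- function(n_trees = 1000L, subsample_frac = 0.7, mtry = NULL,
                      k_folds = 5L, seed = 1L, replace = FALSE) {
  if (n_trees < 1) stop("n_trees must be at least 1")
  if (subsample_frac <= 0 || subsample_frac >= 1)
    stop("subsample_frac must be in (0, 1)")
  if (k_folds < 2) stop("k_folds must be at least 2")
  structure(list(n_trees = as.integer(n_trees),
                 subsample_frac = subsample_frac, mtry = mtry,
                 k_folds = as.integer(k_folds), seed = as.integer(seed),
                 replace = replace),
            class = "rf_config")
}

# internal: coerce inputs, validate two finite classes
rf_inputs <- function(matrix, labels) {
  x <- if (inherits(matrix, "metab_matrix")) {
    if (matrix$state != "log") stop("matrix must be in state 'log'")
    matrix$values
  } else as.matrix(matrix)
  if (any(!is.finite(x))) stop("matrix must have no missing values")
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must contain exactly two classes")
  if (length(y) != nrow(x)) stop("labels length must match samples")
  list(x = x, y = y)
}

#' Per-tree 70/30 holdout evaluation with permutation importance
#'
#' Each tree trains on a stratified random subsample (70\% of each class by
#' default) and predicts the held-out remainder; overall accuracy is the
#' mean per-tree holdout accuracy. Mean decrease accuracy for metabolite j
#' is the mean over trees of (holdout accuracy - holdout accuracy after
#' permuting metabolite j), i.e. a permutation importance evaluated on each
#' tree's own held-out samples. The trees themselves are grown by
#' \pkg{randomForest}; the holdout evaluation and the permutation loop are
#' computed here from the per-tree predictions and in-bag records.
#'
#' @param matrix a \code{\link{metab_matrix}} in state \code{"log"} (or a
#'   plain numeric matrix, samples x metabolites)
#' @param labels two-class vector/factor, one per sample
#' @param config an \code{\link{rf_config}}
#' @return object of class \code{rf_report}: list with \code{scheme}
#'   ("per_tree_holdout"), \code{accuracy}, \code{importance} (named mean
#'   decrease accuracy), \code{seed}, \code{config}
#' @export
train_eval_holdout <- function(matrix, labels, config = rf_config()) {
  d <- rf_inputs(matrix, labels)
  x <- d$x; y <- d$y
  m <- ncol(x)
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(m))) else config$mtry
  sampsize <- pmax(1L, floor(config$subsample_frac * table(y)))
  set.seed(config$seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = config$n_trees, mtry = mtry,
    replace = config$replace, strata = y, sampsize = sampsize,
    keep.inbag = TRUE, keep.forest = TRUE)
  inbag <- rf$inbag                       # n x ntree
  holdout <- inbag == 0

  tree_holdout_acc <- function(xmat) {
    pred <- predict(rf, xmat, predict.all = TRUE)$individual
    hit <- pred == as.character(y)
    colSums(hit & holdout) / colSums(holdout)
  }
  acc_t <- tree_holdout_acc(x)
  accuracy <- mean(acc_t)

  perms <- lapply(seq_len(m), function(j) sample.int(nrow(x)))
  mda <- vapply(seq_len(m), function(j) {
    xp <- x
    xp[, j] <- x[perms[[j]], j]
    mean(acc_t - tree_holdout_acc(xp))
  }, numeric(1))
  names(mda) <- colnames(x)

  structure(list(scheme = "per_tree_holdout", accuracy = accuracy,
                 importance = mda, per_tree_accuracy = acc_t,
                 seed = config$seed, config = config),
            class = "rf_report")
}

#' Stratified k-fold cross-validated random forest
#'
#' Stratified 5-fold (by default) cross-validation: a forest is trained on
#' each training fold (with the same per-tree stratified 70\% subsampling)
#' and evaluated on the held-out fold; accuracy is the mean over folds.
#' Importance is the Gini impurity decrease summed over splits (as reported
#' by \pkg{randomForest}), averaged over the fold models.
#'
#' @inheritParams train_eval_holdout
#' @return object of class \code{rf_report}: \code{scheme} ("cv5"),
#'   \code{accuracy}, per-fold accuracies, \code{importance} (mean Gini
#'   decrease), \code{seed}, \code{config}
#' @export
train_eval_cv <- function(matrix, labels, config = rf_config()) {
  d <- rf_inputs(matrix, labels)
  x <- d$x; y <- d$y
  if (length(y) < config$k_folds) stop("need at least k_folds samples")
  m <- ncol(x)
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(m))) else config$mtry
  set.seed(config$seed)
  # stratified fold assignment: shuffle within class, deal out cyclically
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(config$k_folds), length(idx))
  }
  acc <- numeric(config$k_folds)
  gini <- matrix(0, m, config$k_folds, dimnames = list(colnames(x), NULL))
  for (f in seq_len(config$k_folds)) {
    tr <- fold != f
    ytr <- y[tr]
    sampsize <- pmax(1L, floor(config$subsample_frac * table(ytr)))
    rf <- randomForest::randomForest(
      x = x[tr, , drop = FALSE], y = ytr, ntree = config$n_trees,
      mtry = mtry, replace = config$replace, strata = ytr,
      sampsize = sampsize, importance = FALSE)
    pred <- predict(rf, x[!tr, , drop = FALSE])
    acc[f] <- mean(pred == y[!tr])
    gini[, f] <- rf$importance[, "MeanDecreaseGini"]
  }
  structure(list(scheme = "cv5", accuracy = mean(acc), fold_accuracy = acc,
                 importance = rowMeans(gini), seed = config$seed,
                 config = config),
            class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf("rf_report [%s]: accuracy %.3f (%d trees, seed %d)\n",
              x$scheme, x$accuracy, x$config$n_trees, x$seed))
  top <- names(sort(x$importance, decreasing = TRUE))[seq_len(min(5, length(x$importance)))]
  cat("  top importance:", paste(top, collapse = ", "), "\n")
  invisible(x)
}
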