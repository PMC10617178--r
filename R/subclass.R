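#' Average log abundances within biochemical subclasses
#'
#' For each sample, the subclass score is the arithmetic mean of the log
#' values of its component metabolites — equivalently, the log of the
#' geometric mean of the scaled intensities. Metabolites without an
#' annotation are excluded with a warning.
#'
#' @param matrix a \code{\link{metab_matrix}} with state \code{"log"}
#' @param annotation an \code{\link{annotation_table}}
#' @return samples x subclasses numeric matrix; attribute
#'   \code{components} maps each subclass to its metabolite ids
#' @export
subclass_average <- function(matrix, annotation) {
  stopifnot(inherits(matrix, "metab_matrix"))
  if (matrix$state != "log") stop("matrix must be in state 'log'")
  annotation <- annotation_table(annotation)
  met <- metabolite_ids(matrix)
  idx <- match(met, annotation$metabolite)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " unannotated metabolite(s) excluded from subclass averages")
    keep <- !is.na(idx)
    met <- met[keep]; idx <- idx[keep]
  }
  if (length(met) == 0) stop("no annotated metabolites; empty subclass set")
  sub <- annotation$subclass[idx]
  subs <- unique(sub)
  Y <- matrix$values[, met, drop = FALSE]
  avg <- vapply(subs, function(s) rowMeans(Y[, sub == s, drop = FALSE]),
                numeric(nrow(Y)))
  rownames(avg) <- sample_ids(matrix)
  attr(avg, "components") <- split(met, sub)[subs]
  avg
}

#' Subclass composite regression analysis
#'
#' Each subclass average is regressed on the exposure and covariates. The
#' composite t is the exposure coefficient divided by its standard error;
#' because the outcome is the average of the component metabolites, that
#' standard error mechanically reflects the covariances between them (the
#' SD of the average). Fold difference is exp(beta) with a Wald interval.
#' Subclass q-values come from the same shared-permutation Storey machinery
#' run on the subclass-average matrix. Component counts (how many
#' metabolites of the subclass are individually significant, and in which
#' direction) are taken from the metabolite-level differential table.
#'
#' @param avg_matrix samples x subclasses matrix from
#'   \code{\link{subclass_average}}
#' @param design a \code{\link{metab_design}} on the same samples
#' @param differential metabolite-level \code{differential_table} used for
#'   the component significance counts
#' @param fdr significance threshold applied to the metabolite-level q
#' @param B,seed permutation settings for the subclass-level null
#' @param level confidence level
#' @return data.frame of class \code{subclass_table}: subclass, fold
#'   difference with CI, component counts, composite t and q; attribute
#'   \code{pi0}
#' @export
subclass_test <- function(avg_matrix, design, differential, fdr = 0.05,
                          B = 1000L, seed = 1L, level = 0.95) {
  X <- design_matrix_of(design)
  e <- exposure_index_of(design)
  ids <- if (inherits(design, "metab_design")) design$rows_kept else rownames(avg_matrix)
  if (!all(ids %in% rownames(avg_matrix)))
    stop("design rows not found among subclass-average samples")
  A <- avg_matrix[ids, , drop = FALSE]
  components <- attr(avg_matrix, "components")

  fit <- fit_all_metabolites(A, design)
  tq <- stats::qt(1 - (1 - level) / 2, fit$df)

  Z <- X[, -e, drop = FALSE]
  null <- permutation_null(residualize_matrix(A, Z), residualize(X[, e], Z),
                           B = B, df = fit$df, seed = seed, Z = Z)
  q <- storey_qvalues(fit$t, null)

  counts <- t(vapply(colnames(A), function(s) {
    comp <- components[[s]]
    d <- differential[differential$metabolite %in% comp, , drop = FALSE]
    sig <- d$q < fdr
    c(n_total = length(comp),
      n_significant = sum(sig),
      n_fd_above_1 = sum(sig & d$fold_difference > 1),
      n_fd_below_1 = sum(sig & d$fold_difference < 1))
  }, numeric(4)))

  out <- data.frame(
    subclass = colnames(A),
    fold_difference = exp(fit$beta),
    fold_lo = exp(fit$beta - tq * fit$se),
    fold_hi = exp(fit$beta + tq * fit$se),
    n_total_metabolites = counts[, "n_total"],
    n_significant = counts[, "n_significant"],
    n_fd_above_1 = counts[, "n_fd_above_1"],
    n_fd_below_1 = counts[, "n_fd_below_1"],
    composite_t = fit$t,
    df = fit$df,
    q = as.numeric(q),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "pi0") <- attr(q, "pi0")
  attr(out, "B") <- null$B
  attr(out, "seed") <- seed
  class(out) <- c("subclass_table", "data.frame")
  out
}
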