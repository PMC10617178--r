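#' Exclude metabolites with excessive missingness
#'
#' A metabolite is retained only if its fraction of values below the limit
#' of detection is strictly below \code{max_missing_frac}; at the default
#' 0.8 a metabolite with at least 80\% missing is excluded. Column order of
#' retained metabolites is preserved.
#'
#' @param matrix a raw \code{\link{metab_matrix}}
#' @param max_missing_frac exclusion threshold (exclusive retention bound)
#' @return list with \code{matrix} (filtered) and \code{excluded}
#'   (character vector of dropped metabolite ids)
#' @export
filter_by_missingness <- function(matrix, max_missing_frac = 0.8) {
  stopifnot(inherits(matrix, "metab_matrix"), matrix$state == "raw")
  if (ncol(matrix$values) == 0 || nrow(matrix$values) == 0)
    stop("empty metabolite matrix")
  frac <- colMeans(matrix$missing)
  keep <- frac < max_missing_frac
  list(matrix = subset_metabolites(matrix, keep),
       excluded = metabolite_ids(matrix)[!keep])
}

#' Minimum imputation, median scaling and log transform
#'
#' The three standard preprocessing steps, in order: (1) each missing
#' (below-LOD) entry of metabolite j is replaced by the minimum observed
#' value of j; (2) each metabolite is divided by its median, computed over
#' all n post-imputation values, so the scaled median is exactly 1;
#' (3) natural log. Because undetectable values are low by nature, imputing
#' the observed minimum is a conservative stand-in for a value below the
#' detection limit.
#'
#' All three steps are monotone, so within-metabolite rank order is
#' preserved, and median scaling absorbs any positive rescaling of a raw
#' column, making downstream t-statistics invariant to per-metabolite
#' measurement units.
#'
#' @param matrix a raw \code{\link{metab_matrix}}; every metabolite must
#'   have at least one observed value (filter first)
#' @return a \code{metab_matrix} with state \code{"log"}
#' @export
impute_scale_log <- function(matrix) {
  stopifnot(inherits(matrix, "metab_matrix"), matrix$state == "raw")
  vals <- matrix$values
  miss <- matrix$missing
  n_obs <- colSums(!miss)
  if (any(n_obs == 0))
    stop("metabolite(s) with zero observed values (should have been filtered): ",
         paste(metabolite_ids(matrix)[n_obs == 0], collapse = ", "))
  for (j in seq_len(ncol(vals))) {
    if (any(miss[, j]))
      vals[miss[, j], j] <- min(vals[!miss[, j], j])
  }
  med <- apply(vals, 2, stats::median)
  if (any(med <= 0)) stop("non-positive per-metabolite median")
  vals <- sweep(vals, 2, med, "/")
  metab_matrix(log(vals), miss, state = "log")
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: missingness filter followed by
#' \code{\link{impute_scale_log}}.
#'
#' @inheritParams filter_by_missingness
#' @return list with \code{matrix} (state \code{"log"}) and \code{excluded}
#' @export
preprocess <- function(matrix, max_missing_frac = 0.8) {
  f <- filter_by_missingness(matrix, max_missing_frac)
  list(matrix = impute_scale_log(f$matrix), excluded = f$excluded)
}
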