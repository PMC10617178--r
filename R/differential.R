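#' Fit one metabolite's covariate-adjusted regression
#'
#' Ordinary least squares of a log-abundance vector on the design matrix
#' (intercept + exposure + covariates), with classical homoskedastic
#' standard errors. The residuals are returned for reuse by the permutation
#' machinery. A constant outcome is reported as a degenerate fit with t = 0
#' rather than an error.
#'
#' @param y numeric vector of log abundances, one per design row
#' @param design a \code{\link{metab_design}} (or plain full-rank numeric
#'   matrix whose second column is the exposure)
#' @return list of class \code{metab_fit}: \code{beta} (exposure
#'   coefficient, log scale), \code{se}, \code{t}, \code{df} (n - rank),
#'   \code{coefficients} (full vector), \code{sigma2}, \code{residuals},
#'   \code{degenerate}
#' @export
fit_metabolite <- function(y, design) {
  X <- design_matrix_of(design)
  e <- exposure_index_of(design)
  if (length(y) != nrow(X)) stop("length(y) must equal the number of design rows")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  coefs <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- length(y) - qx$rank
  if (df < 1) stop("no residual degrees of freedom")
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * xtx_inv[e, e])
  degenerate <- sigma2 <= .Machine$double.eps * mean(y^2 + 1)
  t_stat <- if (degenerate || se == 0) 0 else coefs[e] / se
  structure(list(beta = unname(coefs[e]), se = unname(se), t = unname(t_stat),
                 df = df, coefficients = coefs, sigma2 = sigma2,
                 residuals = res, xtx_inv = xtx_inv,
                 degenerate = degenerate),
            class = "metab_fit")
}

# internal accessors so fit functions take either a metab_design or a matrix
design_matrix_of <- function(design) {
  if (inherits(design, "metab_design")) design$matrix
  else as.matrix(design)
}
exposure_index_of <- function(design) {
  if (inherits(design, "metab_design")) design$exposure_index else 2L
}

#' Adjusted geometric means and their confidence intervals
#'
#' Predicted log abundance at exposure = 1 and exposure = 0 with every other
#' design column held at its whole-sample mean, back-transformed by exp.
#' Wald intervals use the prediction variance and t quantiles on the
#' residual degrees of freedom. By construction the ratio of the two
#' adjusted geometric means equals exp(beta) exactly.
#'
#' @param fit a \code{\link{fit_metabolite}} result
#' @param design the design the fit was produced from
#' @param level confidence level
#' @return list with \code{mean1}, \code{ci1}, \code{mean0}, \code{ci0}
#'   (means and length-2 intervals on the intensity scale)
#' @export
adjusted_geomeans <- function(fit, design, level = 0.95) {
  X <- design_matrix_of(design)
  e <- exposure_index_of(design)
  xbar <- colMeans(X)
  x1 <- xbar; x1[e] <- 1
  x0 <- xbar; x0[e] <- 0
  tq <- stats::qt(1 - (1 - level) / 2, fit$df)
  pred <- function(xv) {
    mu <- sum(xv * fit$coefficients)
    se <- sqrt(fit$sigma2 * drop(t(xv) %*% fit$xtx_inv %*% xv))
    c(mean = exp(mu), lo = exp(mu - tq * se), hi = exp(mu + tq * se))
  }
  p1 <- pred(x1); p0 <- pred(x0)
  list(mean1 = unname(p1["mean"]), ci1 = unname(p1[c("lo", "hi")]),
       mean0 = unname(p0["mean"]), ci0 = unname(p0[c("lo", "hi")]))
}

# internal: vectorised OLS of every column of Y on a shared design.
# Returns exposure betas/se/t plus everything needed for adjusted means.
fit_all_metabolites <- function(Y, design) {
  X <- design_matrix_of(design)
  e <- exposure_index_of(design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  df <- nrow(X) - qx$rank
  if (df < 1) stop("no residual degrees of freedom")
  coefs <- qr.coef(qx, Y)                       # p x m
  res <- qr.resid(qx, Y)                        # n x m
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * xtx_inv[e, e])
  degenerate <- sigma2 <= .Machine$double.eps * colMeans(Y^2 + 1)
  t_stat <- ifelse(degenerate | se == 0, 0, coefs[e, ] / se)
  list(beta = coefs[e, ], se = se, t = t_stat, df = df,
       coefficients = coefs, sigma2 = sigma2, residuals = res,
       xtx_inv = xtx_inv, degenerate = degenerate)
}

#' Per-metabolite differential abundance analysis
#'
#' Fits every metabolite's log abundance on the design, computes adjusted
#' geometric means with 95\% confidence intervals, fold differences
#' (exp of the exposure coefficient, i.e. the ratio of adjusted geometric
#' means) with t-based intervals, unadjusted geometric-mean-ratio fold
#' differences, and permutation-based Storey q-values built by permuting the
#' residualized exposure with one shared permutation across metabolites per
#' draw (preserving metabolite-metabolite covariance in the null).
#'
#' @param matrix a \code{\link{metab_matrix}} with state \code{"log"}
#' @param design a \code{\link{metab_design}} built on (a subset of) the
#'   same samples; the matrix is aligned to \code{design$rows_kept}
#' @param annotation optional \code{\link{annotation_table}}; metabolites
#'   without an entry are reported as "unannotated"
#' @param B number of shared permutations for the null
#' @param seed RNG seed for the permutations
#' @param level confidence level for intervals
#' @return data.frame of class \code{differential_table}, one row per
#'   metabolite, with attributes \code{pi0}, \code{B}, \code{df},
#'   \code{seed} and \code{perm_null} (the \code{\link{permutation_null}}
#'   object)
#' @export
run_differential <- function(matrix, design, annotation = NULL,
                             B = 1000L, seed = 1L, level = 0.95) {
  stopifnot(inherits(matrix, "metab_matrix"))
  if (matrix$state != "log") stop("matrix must be preprocessed to state 'log'")
  ids <- design_row_ids(design, matrix)
  matrix <- subset_samples(matrix, match(ids, sample_ids(matrix)))
  Y <- matrix$values
  m <- ncol(Y)
  fit <- fit_all_metabolites(Y, design)

  X <- design_matrix_of(design)
  e <- exposure_index_of(design)
  xbar <- colMeans(X)
  x1 <- xbar; x1[e] <- 1
  x0 <- xbar; x0[e] <- 0
  tq <- stats::qt(1 - (1 - level) / 2, fit$df)
  mu1 <- drop(crossprod(fit$coefficients, x1))
  mu0 <- drop(crossprod(fit$coefficients, x0))
  v1 <- fit$sigma2 * drop(t(x1) %*% fit$xtx_inv %*% x1)
  v0 <- fit$sigma2 * drop(t(x0) %*% fit$xtx_inv %*% x0)

  grp <- X[, e]
  fd_unadj <- exp(colMeans(Y[grp == 1, , drop = FALSE]) -
                  colMeans(Y[grp == 0, , drop = FALSE]))

  # covariance-preserving permutation null on residualized data
  Z <- X[, -e, drop = FALSE]
  x_res <- residualize(X[, e], Z)
  Y_res <- residualize_matrix(Y, Z)
  null <- permutation_null(Y_res, x_res, B = B, df = fit$df, seed = seed,
                           Z = Z)
  q <- storey_qvalues(fit$t, null)
  p_perm <- attr(q, "p_perm")

  met <- metabolite_ids(matrix)
  if (is.null(annotation)) {
    sub <- rep("unannotated", m); maj <- rep("unannotated", m)
  } else {
    annotation <- annotation_table(annotation)
    idx <- match(met, annotation$metabolite)
    if (anyNA(idx))
      warning(sum(is.na(idx)), " metabolite(s) without annotation recorded as 'unannotated'")
    sub <- ifelse(is.na(idx), "unannotated", annotation$subclass[idx])
    maj <- ifelse(is.na(idx), "unannotated", annotation$major_class[idx])
  }

  out <- data.frame(
    metabolite = met, subclass = sub, major_class = maj,
    beta = fit$beta, se = fit$se, t = fit$t, df = fit$df,
    adj_geomean_1 = exp(mu1),
    adj_geomean_1_lo = exp(mu1 - tq * sqrt(v1)),
    adj_geomean_1_hi = exp(mu1 + tq * sqrt(v1)),
    adj_geomean_0 = exp(mu0),
    adj_geomean_0_lo = exp(mu0 - tq * sqrt(v0)),
    adj_geomean_0_hi = exp(mu0 + tq * sqrt(v0)),
    fold_difference = exp(fit$beta),
    fold_lo = exp(fit$beta - tq * fit$se),
    fold_hi = exp(fit$beta + tq * fit$se),
    fd_unadjusted = fd_unadj,
    p_perm = p_perm,
    q = as.numeric(q),
    degenerate = fit$degenerate,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "pi0") <- attr(q, "pi0")
  attr(out, "B") <- null$B
  attr(out, "df") <- fit$df
  attr(out, "seed") <- seed
  attr(out, "perm_null") <- null
  class(out) <- c("differential_table", "data.frame")
  out
}

# internal: align a metab_matrix's samples with a design
design_row_ids <- function(design, matrix) {
  if (inherits(design, "metab_design")) {
    ids <- design$rows_kept
    if (!all(ids %in% sample_ids(matrix)))
      stop("design rows not found among matrix samples")
    ids
  } else {
    if (nrow(as.matrix(design)) != nrow(matrix$values))
      stop("design and matrix have different numbers of samples")
    sample_ids(matrix)
  }
}
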