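#' Model specification for the covariate ladder
#'
#' A named, ordered list of covariates to adjust for, with the exposure
#' (group) always present. \code{model_presets()} ships the four standard
#' specifications of the analysis ladder for study-shaped covariate tables:
#' from a minimally adjusted model (age, sex, batch, study, substudy)
#' through the fully adjusted model (adding BMI, dietary pattern, education,
#' social vulnerability, exercise, coffee, smoking, alcohol, medication use,
#' psychosocial stress and prevalent disease), a dietary-fat variant and a
#' kidney-function (eGFR) variant.
#'
#' @param name label for the specification
#' @param covariates ordered character vector of covariate column names
#'   (excluding the exposure)
#' @param exposure name of the exposure column; must be coded 0/1
#' @return object of class \code{model_spec}
#' @export
model_spec <- function(name, covariates, exposure = "group") {
  stopifnot(is.character(covariates))
  if (exposure %in% covariates)
    stop("exposure must not be repeated among covariates")
  structure(list(name = name, covariates = covariates, exposure = exposure),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
model_presets <- function() {
  simplest <- c("age", "sex", "batch", "study", "substudy")
  lifestyle <- c("bmi", "dietary_pattern", "education", "svi", "exercise",
                 "coffee", "smoking", "alcohol", "med_bp", "med_chol",
                 "med_aspirin", "psychosocial_stress", "prevalent_cvd",
                 "prevalent_cancer", "prevalent_diabetes")
  list(
    simplest   = model_spec("simplest", simplest),
    full       = model_spec("full", c(simplest, lifestyle)),
    full_fat   = model_spec("full_fat",
                            c(simplest, lifestyle,
                              "fat_mono", "fat_poly", "fat_sat")),
    full_egfr  = model_spec("full_egfr", c(simplest, lifestyle, "egfr"))
  )
}

#' Default reference levels for categorical covariates
#'
#' Reference levels determine only the parameterisation of nuisance
#' covariates; the exposure t-statistic is invariant to them. Defaults:
#' never-smoker, never-drinker, non-vegetarian diet, high-school education,
#' Calibration substudy.
#'
#' @return named character vector, covariate -> reference level
#' @export
default_reference_levels <- function() {
  c(smoking = "never", alcohol = "never", dietary_pattern = "non-vegetarian",
    education = "high school", substudy = "Calibration")
}

#' Build the regression design matrix
#'
#' Expands a covariate table into a full-rank numeric design matrix:
#' intercept, 0/1 exposure column, continuous covariates untransformed,
#' categorical covariates as treatment-coded indicators against the stated
#' reference level, ordinal covariates (already numeric, e.g. psychosocial
#' stress 0-2) as a single numeric column. Rows with missing values in any
#' requested covariate are dropped (complete-case, with a message). Columns
#' that are exactly linearly dependent on earlier ones are dropped with a
#' warning when \code{drop_aliased = TRUE} (e.g. a study indicator nested in
#' substudy); with \code{drop_aliased = FALSE} rank deficiency is an error
#' naming the offending columns.
#'
#' @param covariates data.frame of per-sample covariates, rownames =
#'   sample ids; must contain the exposure column coded 0/1
#' @param spec a \code{\link{model_spec}}
#' @param reference_levels named character vector overriding
#'   \code{\link{default_reference_levels}} entries
#' @param drop_aliased drop exactly collinear columns instead of erroring
#' @return object of class \code{metab_design}: list with \code{matrix}
#'   (n x p numeric, full column rank), \code{exposure_index}, \code{rank},
#'   \code{reference_levels}, \code{dropped_columns},
#'   \code{rows_kept} (sample ids retained after complete-case filtering)
#' @export
build_design <- function(covariates, spec,
                         reference_levels = default_reference_levels(),
                         drop_aliased = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  covariates <- as.data.frame(covariates)
  wanted <- c(spec$exposure, spec$covariates)
  missing_cols <- setdiff(wanted, names(covariates))
  if (length(missing_cols))
    stop("unknown covariate(s): ", paste(missing_cols, collapse = ", "))

  cc <- stats::complete.cases(covariates[wanted])
  if (any(!cc))
    message(sprintf("build_design: dropped %d of %d samples with missing covariates",
                    sum(!cc), length(cc)))
  dat <- covariates[cc, wanted, drop = FALSE]
  if (nrow(dat) == 0) stop("no complete-case samples left")

  expo <- dat[[spec$exposure]]
  if (is.factor(expo)) expo <- as.numeric(levels(expo))[expo]
  if (!all(expo %in% c(0, 1)))
    stop("exposure column must be coded 0/1")

  cols <- list("(Intercept)" = rep(1, nrow(dat)))
  cols[[spec$exposure]] <- as.numeric(expo)
  refs <- default_reference_levels()
  refs[names(reference_levels)] <- reference_levels
  used_refs <- character(0)
  for (v in spec$covariates) {
    x <- dat[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- x
    } else {
      f <- if (is.factor(x)) droplevels(x) else factor(x)
      if (!is.na(refs[v]) && refs[v] %in% levels(f))
        f <- stats::relevel(f, ref = refs[v])
      used_refs[v] <- levels(f)[1]
      for (l in levels(f)[-1])
        cols[[paste0(v, l)]] <- as.numeric(f == l)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  rownames(X) <- rownames(dat)

  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    if (any(dep %in% c("(Intercept)", spec$exposure)))
      stop("exposure or intercept aliased with covariates: ",
           paste(dep, collapse = ", "))
    if (!drop_aliased)
      stop("design is rank deficient; collinear columns: ",
           paste(dep, collapse = ", "))
    warning("dropping aliased design column(s): ", paste(dep, collapse = ", "))
    X <- X[, setdiff(colnames(X), dep), drop = FALSE]
    qr_x <- qr(X)
    dropped <- dep
  } else {
    dropped <- character(0)
  }
  structure(list(matrix = X,
                 exposure_index = match(spec$exposure, colnames(X)),
                 rank = qr_x$rank,
                 reference_levels = used_refs,
                 dropped_columns = dropped,
                 rows_kept = rownames(dat),
                 spec = spec),
            class = "metab_design")
}

#' @export
print.metab_design <- function(x, ...) {
  cat(sprintf("metab_design '%s': %d samples x %d columns (rank %d)\n",
              x$spec$name, nrow(x$matrix), ncol(x$matrix), x$rank))
  cat("  exposure:", colnames(x$matrix)[x$exposure_index], "\n")
  if (length(x$dropped_columns))
    cat("  dropped aliased:", paste(x$dropped_columns, collapse = ", "), "\n")
  invisible(x)
}
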