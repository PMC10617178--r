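#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the design of a two-group plasma metabolomics cohort:
#' 171 + 179 participants, 892 metabolites organised in 92 biochemical
#' subclasses, block-equicorrelated log intensities within subclass, a
#' minority of metabolites carrying a group effect on the log scale, and
#' covariates whose distributions differ between the groups (so that
#' covariate adjustment is exercised non-trivially).
#'
#' @param n_per_group integer pair: samples in group 1 (exposure = 1) and
#'   group 0.
#' @param n_metabolites number of metabolites.
#' @param n_subclasses number of biochemical subclasses; metabolites are
#'   spread over subclasses as evenly as possible.
#' @param within_subclass_correlation equicorrelation of log intensities
#'   between metabolites of the same subclass, in [0, 1).
#' @param frac_nonnull fraction of metabolites with a true group effect.
#' @param effect_size_log_sd magnitude of the group effect, in units of the
#'   residual SD on the log scale; signs are random (fair coin) per
#'   metabolite.
#' @param covariate_spec list of covariate descriptors, each a list with
#'   \code{name}, \code{type} (\code{"continuous"}, \code{"binary"},
#'   \code{"categorical"}, \code{"ordinal"}), \code{assoc} (association with
#'   group: mean shift in SD units for continuous, logit shift otherwise)
#'   and, for categorical/ordinal, \code{levels}. See
#'   \code{default_covariate_spec()}.
#' @param lod_missing_frac fraction of each metabolite's lowest values
#'   censored as below the limit of detection, in [0, 1).
#' @param batch_count number of analytic batches (additive log-scale shift).
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#'
#' @return an object of class \code{sim_config}
#' @export
sim_config <- function(n_per_group = c(171L, 179L),
                       n_metabolites = 892L,
                       n_subclasses = 92L,
                       within_subclass_correlation = 0.5,
                       frac_nonnull = 0.1,
                       effect_size_log_sd = 0.5,
                       covariate_spec = default_covariate_spec(),
                       lod_missing_frac = 0.2,
                       batch_count = 2L,
                       seed = 1L) {
  bad <- function(field, why) stop(sprintf("invalid sim_config: '%s' %s", field, why))
  if (length(n_per_group) != 2 || any(n_per_group < 1)) bad("n_per_group", "must be two positive integers")
  if (n_metabolites < 1) bad("n_metabolites", "must be positive")
  if (n_subclasses < 1 || n_subclasses > n_metabolites) bad("n_subclasses", "must be in [1, n_metabolites]")
  if (within_subclass_correlation < 0 || within_subclass_correlation >= 1)
    bad("within_subclass_correlation", "must be in [0, 1)")
  if (frac_nonnull < 0 || frac_nonnull > 1) bad("frac_nonnull", "must be in [0, 1]")
  if (effect_size_log_sd < 0) bad("effect_size_log_sd", "must be nonnegative")
  if (lod_missing_frac < 0 || lod_missing_frac >= 1) bad("lod_missing_frac", "must be in [0, 1)")
  if (batch_count < 1) bad("batch_count", "must be positive")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_metabolites = as.integer(n_metabolites),
                 n_subclasses = as.integer(n_subclasses),
                 within_subclass_correlation = within_subclass_correlation,
                 frac_nonnull = frac_nonnull,
                 effect_size_log_sd = effect_size_log_sd,
                 covariate_spec = covariate_spec,
                 lod_missing_frac = lod_missing_frac,
                 batch_count = as.integer(batch_count),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default covariate specification
#'
#' Six covariates moderately associated with group, emulating the kind of
#' confounding seen in observational cohorts (the groups differ in age,
#' coffee consumption, social vulnerability, medication use, smoking
#' history). Association strengths are mean shifts in SD units (continuous)
#' or logit shifts (binary/categorical/ordinal).
#'
#' @return list of covariate descriptors for \code{\link{sim_config}}
#' @export
default_covariate_spec <- function() {
  list(
    list(name = "age",     type = "continuous",  assoc = -0.3),
    list(name = "sex",     type = "binary",      assoc = 0.1),
    list(name = "bmi",     type = "continuous",  assoc = 0.2),
    list(name = "coffee",  type = "continuous",  assoc = -0.6),
    list(name = "svi",     type = "continuous",  assoc = 0.3),
    list(name = "smoking", type = "categorical", assoc = 0.5,
         levels = c("never", "former", "current"))
  )
}

# internal: draw one covariate given the 0/1 group vector; returns a list
# with the user-facing column and the standardized numeric encoding(s) used
# for metabolite effects.
draw_covariate <- function(spec, group) {
  n <- length(group)
  switch(spec$type,
    continuous = {
      z <- stats::rnorm(n) + spec$assoc * group
      list(column = z, encoded = matrix(z, ncol = 1,
                                        dimnames = list(NULL, spec$name)))
    },
    binary = {
      p <- stats::plogis(0 + spec$assoc * group)
      z <- stats::rbinom(n, 1L, p)
      list(column = z, encoded = matrix(as.numeric(z), ncol = 1,
                                        dimnames = list(NULL, spec$name)))
    },
    categorical = ,
    ordinal = {
      lev <- spec$levels
      k <- length(lev)
      if (k < 2) stop("categorical covariate needs >= 2 levels: ", spec$name)
      # logits shifted by group, increasing towards later levels
      shift <- spec$assoc * (seq_len(k) - mean(seq_len(k)))
      z <- vapply(group, function(g) {
        logit <- g * shift
        pr <- exp(logit - max(logit)); pr <- pr / sum(pr)
        sample.int(k, 1L, prob = pr)
      }, integer(1))
      col <- factor(lev[z], levels = lev)
      if (spec$type == "ordinal") {
        enc <- matrix(as.numeric(z) - 1, ncol = 1, dimnames = list(NULL, spec$name))
        list(column = as.numeric(z) - 1, encoded = enc)
      } else {
        enc <- vapply(lev[-1], function(l) as.numeric(col == l), numeric(n))
        colnames(enc) <- paste0(spec$name, "_", lev[-1])
        list(column = col, encoded = enc)
      }
    },
    stop("unknown covariate type: ", spec$type)
  )
}

#' Generate a synthetic two-group metabolomics cohort
#'
#' Intensities are lognormal: the log intensity of metabolite j in sample i
#' is baseline_j + batch shift + covariate effects + group effect + noise,
#' where the noise has unit variance and equicorrelation
#' \code{within_subclass_correlation} between metabolites sharing a
#' subclass (independent across subclasses). Covariate effects on the log
#' scale make the configured group-associated covariates genuine
#' confounders. Ground truth (which metabolites carry an effect, and its
#' signed log-scale size) is returned alongside.
#'
#' @param config a \code{\link{sim_config}}
#' @return list with elements \code{matrix} (a raw, complete
#'   \code{\link{metab_matrix}}), \code{covariates} (data.frame with
#'   \code{group}, \code{batch} and the configured covariates),
#'   \code{annotation} (metabolite, subclass, major_class) and \code{truth}
#'   (list: \code{nonnull_ids}, \code{true_effects} named vector — zero
#'   exactly off the non-null set —, \code{subclass_assignment}).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n1 <- config$n_per_group[1]; n0 <- config$n_per_group[2]
  n <- n1 + n0
  m <- config$n_metabolites
  group <- c(rep(1L, n1), rep(0L, n0))
  sample_id <- sprintf("S%03d", seq_len(n))
  metabolite <- sprintf("met_%04d", seq_len(m))

  # subclass layout: as even as possible, contiguous blocks
  subclass_idx <- sort(rep_len(seq_len(config$n_subclasses), m))
  subclass <- sprintf("subclass_%02d", subclass_idx)
  major <- sprintf("class_%d", ((subclass_idx - 1L) %% 8L) + 1L)
  annotation <- data.frame(metabolite = metabolite, subclass = subclass,
                           major_class = major, stringsAsFactors = FALSE)

  # covariates
  cov_cols <- list(group = group)
  enc <- matrix(0, n, 0)
  for (spec in config$covariate_spec) {
    d <- draw_covariate(spec, group)
    cov_cols[[spec$name]] <- d$column
    enc <- cbind(enc, d$encoded)
  }
  batch <- sample.int(config$batch_count, n, replace = TRUE)
  cov_cols$batch <- as.numeric(batch)
  covariates <- as.data.frame(cov_cols, stringsAsFactors = FALSE)
  rownames(covariates) <- sample_id

  # ground-truth group effects: fixed magnitude, random sign
  k_nonnull <- round(config$frac_nonnull * m)
  nonnull <- if (k_nonnull > 0) sort(sample.int(m, k_nonnull)) else integer(0)
  delta <- numeric(m)
  if (k_nonnull > 0)
    delta[nonnull] <- config$effect_size_log_sd *
      sample(c(-1, 1), k_nonnull, replace = TRUE)
  names(delta) <- metabolite

  # covariate effects on log intensities: each encoded covariate column hits
  # a random half of the metabolites with N(0, 0.15) coefficients
  gamma <- matrix(0, ncol(enc), m)
  for (c_i in seq_len(ncol(enc))) {
    hit <- sample.int(m, floor(m / 2))
    gamma[c_i, hit] <- stats::rnorm(length(hit), 0, 0.15)
  }

  # batch shifts on the log scale
  batch_shift <- matrix(stats::rnorm(config$batch_count * m, 0, 0.2),
                        config$batch_count, m)

  # block-equicorrelated unit-variance noise
  rho <- config$within_subclass_correlation
  shared <- matrix(stats::rnorm(n * config$n_subclasses), n, config$n_subclasses)
  eps <- sqrt(rho) * shared[, subclass_idx, drop = FALSE] +
    sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)

  baseline <- stats::rnorm(m, 10, 1)            # log peak-density scale
  loga <- matrix(baseline, n, m, byrow = TRUE) +
    batch_shift[batch, , drop = FALSE] +
    enc %*% gamma +
    outer(as.numeric(group), delta) +
    eps
  values <- exp(loga)
  dimnames(values) <- list(sample_id, metabolite)

  mat <- metab_matrix(values, matrix(FALSE, n, m), state = "raw")
  truth <- list(nonnull_ids = metabolite[nonnull],
                true_effects = delta,
                subclass_assignment = stats::setNames(subclass, metabolite))
  list(matrix = mat, covariates = covariates, annotation = annotation,
       truth = truth)
}

#' Censor values below a per-metabolite limit of detection
#'
#' Deterministic left-censoring: for each metabolite the lowest
#' \code{floor(lod_missing_frac * n)} values are marked missing. This
#' emulates "undetectable" measurements, which are low by construction, not
#' missing at random. Ties at the censoring boundary are broken by sample
#' order (the first occurrences are censored).
#'
#' @param matrix a complete raw \code{\link{metab_matrix}}
#' @param lod_missing_frac fraction in [0, 1)
#' @param seed unused for the default deterministic rule; accepted so the
#'   call signature is stable under future randomised censoring variants
#' @return a raw \code{metab_matrix} with the mask updated and censored
#'   values set to NA
#' @export
apply_lod_censoring <- function(matrix, lod_missing_frac, seed = NULL) {
  stopifnot(inherits(matrix, "metab_matrix"), matrix$state == "raw")
  if (any(matrix$missing)) stop("input matrix must be complete (no missing values)")
  if (lod_missing_frac >= 1) stop("lod_missing_frac must be < 1")
  if (lod_missing_frac < 0) stop("lod_missing_frac must be >= 0")
  n <- nrow(matrix$values)
  k <- floor(lod_missing_frac * n)
  if (k == 0) return(matrix)
  vals <- matrix$values
  miss <- matrix$missing
  for (j in seq_len(ncol(vals))) {
    low <- order(vals[, j])[seq_len(k)]
    miss[low, j] <- TRUE
    vals[low, j] <- NA_real_
  }
  metab_matrix(vals, miss, state = "raw")
}
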