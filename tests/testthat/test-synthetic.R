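test_that("cohort generation is bit-identical under a fixed config", {
  cfg <- sim_config(n_per_group = c(30, 30), n_metabolites = 40,
                    n_subclasses = 8, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$truth, b$truth)
})

test_that("invalid configs are rejected naming the field", {
  expect_error(sim_config(within_subclass_correlation = 1), "within_subclass_correlation")
  expect_error(sim_config(frac_nonnull = 1.2), "frac_nonnull")
  expect_error(sim_config(n_subclasses = 50, n_metabolites = 10), "n_subclasses")
  expect_error(sim_config(lod_missing_frac = 1), "lod_missing_frac")
})

test_that("ground truth matches the generating model", {
  coh <- generate_cohort(sim_config(n_per_group = c(20, 20), n_metabolites = 50,
                                    n_subclasses = 10, frac_nonnull = 0.2, seed = 3))
  tr <- coh$truth
  expect_length(tr$nonnull_ids, 10)
  expect_true(all(tr$true_effects[tr$nonnull_ids] != 0))
  expect_true(all(tr$true_effects[setdiff(names(tr$true_effects), tr$nonnull_ids)] == 0))
  expect_identical(unname(tr$subclass_assignment[coh$annotation$metabolite]),
                   coh$annotation$subclass)
  # frac_nonnull = 0 leaves nothing non-null
  coh0 <- generate_cohort(sim_config(n_per_group = c(10, 10), n_metabolites = 20,
                                     n_subclasses = 4, frac_nonnull = 0, seed = 1))
  expect_length(coh0$truth$nonnull_ids, 0)
  expect_true(all(coh0$truth$true_effects == 0))
})

test_that("within-subclass correlation matches the configured value", {
  for (rho in c(0, 0.5)) {
    coh <- generate_cohort(sim_config(n_per_group = c(171, 179),
                                      n_metabolites = 60, n_subclasses = 6,
                                      within_subclass_correlation = rho,
                                      frac_nonnull = 0, seed = 5))
    lg <- log(coh$matrix$values)
    # partial out the generating covariate/batch structure by correlating
    # within one batch-free direction: residualize on observed covariates
    Z <- build_design(coh$covariates,
                      model_spec("z", c("age", "sex", "bmi", "coffee", "svi",
                                        "smoking", "batch")))$matrix
    R <- qr.resid(qr(Z), lg)
    cors <- c()
    for (s in unique(coh$annotation$subclass)) {
      cols <- which(coh$annotation$subclass == s)
      cm <- stats::cor(R[, cols])
      cors <- c(cors, cm[upper.tri(cm)])
    }
    expect_lt(abs(mean(cors) - rho), 0.05)
  }
})

test_that("global-null two-sample t variance matches the t distribution", {
  coh <- generate_cohort(sim_config(n_per_group = c(30, 30), n_metabolites = 1200,
                                    n_subclasses = 1200, frac_nonnull = 0,
                                    within_subclass_correlation = 0,
                                    covariate_spec = list(), batch_count = 1,
                                    seed = 19))
  lg <- log(coh$matrix$values)
  g <- coh$covariates$group
  tt <- apply(lg, 2, pooled_two_sample_t, g = g)
  df <- 58
  expect_lt(abs(stats::var(tt) / (df / (df - 2)) - 1), 0.10)
})

test_that("LOD censoring removes exactly the lowest values", {
  coh <- generate_cohort(sim_config(n_per_group = c(171, 179), n_metabolites = 25,
                                    n_subclasses = 5, seed = 8))
  cen <- apply_lod_censoring(coh$matrix, 0.2)
  expect_equal(unname(colSums(cen$missing)), rep(70, 25))
  for (j in seq_len(25)) {
    censored <- coh$matrix$values[cen$missing[, j], j]
    observed <- cen$values[!cen$missing[, j], j]
    expect_true(all(observed > max(censored)))
  }
  # untouched otherwise
  expect_identical(cen$values[!cen$missing], coh$matrix$values[!cen$missing])
  # frac 0 is the identity
  expect_identical(apply_lod_censoring(coh$matrix, 0), coh$matrix)
  expect_error(apply_lod_censoring(coh$matrix, 1), "lod_missing_frac")
})

test_that("heavy censoring pushes every metabolite past the 80% filter", {
  coh <- generate_cohort(sim_config(n_per_group = c(171, 179), n_metabolites = 10,
                                    n_subclasses = 2, seed = 2))
  cen <- apply_lod_censoring(coh$matrix, 0.85)
  f <- filter_by_missingness(cen)
  expect_equal(ncol(f$matrix$values), 0)
  expect_length(f$excluded, 10)
})

test_that("OLS on the generating design recovers true effects", {
  set.seed(99)
  biases <- replicate(20, {
    seed <- sample.int(1e6, 1)
    coh <- generate_cohort(sim_config(n_per_group = c(175, 175), n_metabolites = 40,
                                      n_subclasses = 8, frac_nonnull = 0.5,
                                      effect_size_log_sd = 0.5, seed = seed))
    des <- build_design(coh$covariates,
                        model_spec("gen", c("age", "sex", "bmi", "coffee", "svi",
                                            "smoking", "batch")))
    fit <- metabperm:::fit_all_metabolites(log(coh$matrix$values), des)
    nn <- coh$truth$nonnull_ids
    mean((fit$beta[nn] - coh$truth$true_effects[nn]) *
           sign(coh$truth$true_effects[nn]))
  })
  expect_lt(abs(mean(biases)), 0.05)
})
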