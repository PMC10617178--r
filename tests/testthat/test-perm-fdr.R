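test_that("residualize projects out the covariate space", {
  set.seed(41)
  n <- 30
  Z <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  v <- rnorm(n)
  r <- residualize(v, Z)
  expect_lt(max(abs(crossprod(Z, r))), 1e-8 * n)
  expect_equal(r, unname(resid(lm(v ~ Z - 1))), tolerance = 1e-10)
  # a column of Z residualizes to zero; an orthogonal vector is unchanged
  expect_equal(residualize(Z[, 2], Z), rep(0, n), tolerance = 1e-10)
  v_orth <- residualize(rnorm(n), Z)
  expect_equal(residualize(v_orth, Z), v_orth, tolerance = 1e-10)
  expect_error(residualize(v, cbind(Z, Z[, 2])), "rank deficient")
})

test_that("the unpermuted Frisch-Waugh statistic equals the OLS exposure t", {
  coh <- make_toy_cohort(seed = 43)
  X <- coh$design$matrix
  e <- coh$design$exposure_index
  Z <- X[, -e, drop = FALSE]
  Y <- coh$log_matrix$values
  fit <- metabperm:::fit_all_metabolites(Y, coh$design)
  t_fwl <- metabperm:::fw_t(metabperm:::residualize_matrix(Y, Z),
                            residualize(X[, e], Z), fit$df)
  expect_equal(unname(t_fwl), unname(fit$t), tolerance = 1e-8)
})

test_that("permutation null is reproducible and degenerate inputs are handled", {
  set.seed(44)
  Y <- matrix(rnorm(40 * 6), 40, 6)
  x <- rnorm(40)
  a <- permutation_null(Y, x, B = 20, df = 38, seed = 5)
  b <- permutation_null(Y, x, B = 20, df = 38, seed = 5)
  expect_identical(a$t_null, b$t_null)
  expect_error(permutation_null(Y, x, B = 0, df = 38), "B")
  # zero exposure residual: all null t are 0
  z <- permutation_null(Y, rep(0, 40), B = 10, df = 38, seed = 1)
  expect_true(all(z$t_null == 0))
})

test_that("pooled null |t| quantiles match the t distribution under the null", {
  set.seed(45)
  n <- 60; m <- 150
  Z <- cbind(1, rnorm(n))
  x <- residualize(rbinom(n, 1, 0.5), Z)
  Y <- metabperm:::residualize_matrix(matrix(rnorm(n * m), n, m), Z)
  df <- n - 3   # intercept + covariate + exposure
  null <- permutation_null(Y, x, B = 200, df = df, seed = 2)
  pooled <- abs(as.vector(null$t_null))
  for (p in c(0.5, 0.9, 0.99)) {
    emp <- quantile(pooled, p, names = FALSE)
    theo <- qt(1 - (1 - p) / 2, df)
    expect_lt(abs(emp - theo) / theo, 0.05)
  }
})

test_that("pi0 is ~1 under the null, ~0.5 under a half-signal mixture", {
  set.seed(46)
  n <- 50; m <- 600
  Z <- matrix(1, n, 1)
  x <- residualize(rbinom(n, 1, 0.5), Z)
  Y <- metabperm:::residualize_matrix(matrix(rnorm(n * m), n, m), Z)
  null <- permutation_null(Y, x, B = 100, df = n - 2, seed = 3)
  t_null_draw <- null$t_null[1, ]
  expect_lt(abs(estimate_pi0(t_null_draw, null) - 1), 0.1)
  t_mix <- c(null$t_null[2, seq_len(m / 2)], rep(50, m / 2))
  expect_lt(abs(estimate_pi0(t_mix, null) - 0.5), 0.1)
  # all observed enormous: pi0 hits its 1/m floor
  expect_equal(estimate_pi0(rep(100, m), null), 1 / m)
  degenerate <- structure(list(t_null = matrix(1, 10, 5), B = 10L,
                               df = 48, seed = 1L), class = "perm_null")
  expect_error(estimate_pi0(rep(1, 5), degenerate), "degenerate")
})

test_that("q-values are monotone in |t| with ties sharing a value", {
  set.seed(47)
  n <- 40; m <- 80
  Z <- matrix(1, n, 1)
  x <- residualize(rbinom(n, 1, 0.5), Z)
  Y <- metabperm:::residualize_matrix(matrix(rnorm(n * m), n, m), Z)
  null <- permutation_null(Y, x, B = 100, df = n - 2, seed = 4)
  t_obs <- c(rnorm(m - 2), 3.3, -3.3)   # a tie in |t|
  q <- storey_qvalues(t_obs, null)
  ord <- order(abs(t_obs), decreasing = TRUE)
  expect_true(all(diff(q[ord]) >= -1e-15))
  expect_equal(q[m - 1], q[m])
  expect_equal(which.min(q), which.max(abs(t_obs)))
  expect_true(all(q >= 0 & q <= 1))
})

test_that("a single far-outlying statistic gets the permutation-floor q", {
  set.seed(48)
  n <- 30
  Z <- matrix(1, n, 1)
  x <- residualize(rbinom(n, 1, 0.5), Z)
  y <- metabperm:::residualize_matrix(matrix(rnorm(n), n, 1), Z)
  B <- 200
  null <- permutation_null(y, x, B = B, df = n - 2, seed = 5)
  q <- storey_qvalues(1e4, null, pi0 = 1)
  expect_equal(as.numeric(q), 1 / (B + 1), tolerance = 1e-12)
})

test_that("null t rows preserve within-block correlation", {
  coh <- generate_cohort(sim_config(n_per_group = c(100, 100), n_metabolites = 40,
                                    n_subclasses = 4,
                                    within_subclass_correlation = 0.9,
                                    frac_nonnull = 0, covariate_spec = list(),
                                    batch_count = 1, seed = 49))
  lg <- impute_scale_log(coh$matrix)
  des <- build_design(coh$covariates, model_spec("n", character(0)))
  X <- des$matrix
  Z <- X[, 1, drop = FALSE]
  null <- permutation_null(metabperm:::residualize_matrix(lg$values, Z),
                           residualize(X[, 2], Z), B = 300,
                           df = nrow(X) - 2, seed = 6)
  cors <- c()
  for (s in unique(coh$annotation$subclass)) {
    cols <- which(coh$annotation$subclass == s)
    cm <- cor(null$t_null[, cols])
    cors <- c(cors, cm[upper.tri(cm)])
  }
  expect_gt(mean(cors), 0.5)
})

test_that("discoveries grow with effect size and sample size", {
  run_one <- function(n_half, effect) {
    coh <- generate_cohort(sim_config(n_per_group = c(n_half, n_half),
                                      n_metabolites = 120, n_subclasses = 12,
                                      frac_nonnull = 0.2,
                                      effect_size_log_sd = effect, seed = 50))
    des <- build_design(coh$covariates,
                        model_spec("l", c("age", "sex", "bmi", "coffee",
                                          "svi", "smoking", "batch")))
    dt <- run_differential(impute_scale_log(coh$matrix), des, coh$annotation,
                           B = 150, seed = 7)
    sum(dt$q < 0.05)
  }
  ladder_effect <- c(run_one(80, 0.2), run_one(80, 0.6), run_one(80, 1.2))
  expect_true(all(diff(ladder_effect) >= 0))
  ladder_n <- c(run_one(30, 0.6), run_one(120, 0.6))
  expect_true(all(diff(ladder_n) >= 0))
})
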