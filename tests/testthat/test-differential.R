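test_that("a two-group fit matches the closed-form pooled t", {
  y <- c(1, 2, 3, 4)
  X <- cbind("(Intercept)" = 1, group = c(0, 0, 1, 1))
  fit <- fit_metabolite(y, X)
  expect_equal(fit$beta, 2)
  expect_equal(fit$df, 2)
  expect_equal(fit$t, pooled_two_sample_t(y, X[, "group"]), tolerance = 1e-12)
})

test_that("a constant outcome is a degenerate fit with t = 0", {
  X <- cbind(1, c(0, 0, 1, 1))
  fit <- fit_metabolite(rep(5, 4), X)
  expect_true(fit$degenerate)
  expect_equal(fit$t, 0)
})

test_that("full-model t equals the Frisch-Waugh residualized t", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    p <- sample(2:6, 1)
    Z <- cbind(1, matrix(rnorm(n * p), n, p))
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) x[1:2] <- c(0, 1)
    y <- rnorm(n)
    X <- cbind(Z[, 1, drop = FALSE], group = x, Z[, -1, drop = FALSE])
    fit <- fit_metabolite(y, X)
    y_res <- residualize(y, Z)
    x_res <- residualize(x, Z)
    r <- sum(x_res * y_res) / sqrt(sum(x_res^2) * sum(y_res^2))
    t_fwl <- r * sqrt(fit$df / (1 - r^2))
    expect_equal(fit$t, t_fwl, tolerance = 1e-8)
  }
})

test_that("adjusted geometric means back-transform correctly", {
  set.seed(8)
  n <- 8
  X <- cbind("(Intercept)" = 1, group = rep(c(1, 0), each = 4),
             z = rnorm(n))
  y <- 0.3 + log(2) * X[, "group"] + 0.5 * X[, "z"] + rnorm(n, sd = 0.1)
  fit <- fit_metabolite(y, X)
  gm <- adjusted_geomeans(fit, X)
  # brute-force prediction at the covariate mean
  beta <- solve(crossprod(X), crossprod(X, y))
  x1 <- c(1, 1, mean(X[, "z"])); x0 <- c(1, 0, mean(X[, "z"]))
  expect_equal(gm$mean1, exp(sum(x1 * beta)), tolerance = 1e-10)
  expect_equal(gm$mean0, exp(sum(x0 * beta)), tolerance = 1e-10)
  # ratio of adjusted geometric means is exactly exp(beta)
  expect_equal(gm$mean1 / gm$mean0, exp(fit$beta), tolerance = 1e-12)
  # zero effect means equal means
  y0 <- X[, "z"] + rnorm(n, sd = 0.1)
  f0 <- fit_metabolite(y0, X)
  f0$coefficients[2] <- 0; f0$beta <- 0
  g0 <- adjusted_geomeans(f0, X)
  expect_equal(g0$mean1, g0$mean0, tolerance = 1e-12)
})

test_that("the differential table satisfies its fold-difference identities", {
  coh <- make_toy_cohort(seed = 12)
  dt <- run_differential(coh$log_matrix, coh$design, coh$annotation,
                         B = 100, seed = 1)
  expect_equal(dt$fold_difference, exp(dt$beta), tolerance = 1e-12)
  tq <- qt(0.975, dt$df[1])
  expect_equal(dt$fold_lo, exp(dt$beta - tq * dt$se), tolerance = 1e-12)
  expect_equal(dt$fold_hi, exp(dt$beta + tq * dt$se), tolerance = 1e-12)
  expect_true(all(dt$fold_lo < dt$fold_difference & dt$fold_difference < dt$fold_hi))
  expect_equal(dt$adj_geomean_1 / dt$adj_geomean_0, dt$fold_difference,
               tolerance = 1e-12)
  expect_equal(dt$subclass, coh$annotation$subclass)
})

test_that("swapping exposure labels inverts folds and negates t", {
  coh <- make_toy_cohort(seed = 13)
  cv2 <- coh$covariates
  cv2$group <- 1 - cv2$group
  des2 <- build_design(cv2, coh$design$spec)
  dt1 <- run_differential(coh$log_matrix, coh$design, coh$annotation,
                          B = 50, seed = 1)
  dt2 <- run_differential(coh$log_matrix, des2, coh$annotation,
                          B = 50, seed = 1)
  expect_equal(dt2$fold_difference, 1 / dt1$fold_difference, tolerance = 1e-10)
  expect_equal(dt2$t, -dt1$t, tolerance = 1e-10)
})

test_that("confidence intervals shrink as n grows", {
  coh <- make_toy_cohort(n_per_group = c(150, 150), seed = 14)
  sub_ids <- sample_ids(coh$log_matrix)[c(1:50, 151:200)]
  cv_small <- coh$covariates[sub_ids, ]
  spec <- coh$design$spec
  d_small <- build_design(cv_small, spec)
  dt_small <- run_differential(coh$log_matrix, d_small, coh$annotation,
                               B = 50, seed = 1)
  dt_big <- run_differential(coh$log_matrix, coh$design, coh$annotation,
                             B = 50, seed = 1)
  width_small <- log(dt_small$fold_hi) - log(dt_small$fold_lo)
  width_big <- log(dt_big$fold_hi) - log(dt_big$fold_lo)
  expect_gt(mean(width_small > width_big), 0.95)
})

test_that("type-I error is calibrated under the global null", {
  coh <- generate_cohort(sim_config(n_per_group = c(100, 100), n_metabolites = 1000,
                                    n_subclasses = 1000, frac_nonnull = 0,
                                    within_subclass_correlation = 0,
                                    covariate_spec = list(), batch_count = 1,
                                    seed = 15))
  des <- build_design(coh$covariates, model_spec("null", character(0)))
  fit <- metabperm:::fit_all_metabolites(log(coh$matrix$values), des)
  frac <- mean(abs(fit$t) > qt(0.975, fit$df))
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("signs of estimated effects track the truth at effect 1 SD", {
  coh <- make_toy_cohort(n_per_group = c(175, 175), m = 100, n_sub = 10,
                         frac_nonnull = 0.3, effect = 1, seed = 16)
  dt <- run_differential(coh$log_matrix, coh$design, coh$annotation,
                         B = 50, seed = 1)
  nn <- coh$truth$nonnull_ids
  agree <- sign(dt$beta[match(nn, dt$metabolite)]) ==
    sign(coh$truth$true_effects[nn])
  expect_gte(mean(agree), 0.95)
})

test_that("unannotated metabolites are reported with a warning", {
  coh <- make_toy_cohort(seed = 17)
  ann <- coh$annotation[-1, ]
  expect_warning(dt <- run_differential(coh$log_matrix, coh$design, ann,
                                        B = 20, seed = 1),
                 "unannotated")
  expect_equal(dt$subclass[1], "unannotated")
})
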