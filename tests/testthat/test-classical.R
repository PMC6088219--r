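implied_pop_cov <- function(tr) {
  Phi_omega <- matrix(0, 3, 3)
  Phi_omega[2:3, 2:3] <- tr$Phi_xi
  pg <- tr$Phi_xi %*% tr$gamma
  Phi_omega[1, 1] <- tr$var_eta
  Phi_omega[1, 2:3] <- pg; Phi_omega[2:3, 1] <- pg
  tr$Lambda %*% Phi_omega %*% t(tr$Lambda) + diag(tr$Psi)
}

test_that("population covariance is a zero-discrepancy fixed point", {
  tr <- synthetic_truth(n = 2000,
                        error = quantsem:::make_error("normal", sd = 0.6),
                        seed = 1)
  spec <- quantsem:::default_qsem_spec()
  fit <- fit_mean_sem(spec = spec, S = implied_pop_cov(tr), n = 2000)
  expect_lt(fit$F_ML, 1e-8)
  expect_equal(unname(fit$estimates$gamma), tr$gamma, tolerance = 1e-4)
  factor_of <- c(rep(1, 3), rep(2, 7), rep(3, 4))
  expect_lt(max(abs(fit$estimates$Lambda[cbind(1:14, factor_of)] - 1)),
            1e-3)
  expect_equal(fit$estimates$Phi_xi, tr$Phi_xi, tolerance = 1e-3)
})

test_that("maximum likelihood recovers structural coefficients from data", {
  tr <- synthetic_truth(n = 2000,
                        error = quantsem:::make_error("normal", sd = 0.6),
                        seed = 23)
  dat <- fit_data_from(generate_dataset(tr))
  spec <- quantsem:::default_qsem_spec()
  fit <- fit_mean_sem(dat, spec)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimates$gamma - tr$gamma)), 0.1)
  # education dummies contrast against a 7.7% reference category, so their
  # ML standard error is ~0.055 at n = 2000; allow ~2.5 SE
  expect_lt(max(abs(fit$estimates$b - tr$b)), 0.15)
  expect_gt(fit$df, 0)
  idx <- fit_indices(fit)
  expect_true(idx$acceptable)  # data generated from the fitted structure
})

test_that("fit indices match their defining arithmetic", {
  # chisq = df: perfect-fit limit
  f <- list(chisq = 50, df = 50, chisq_baseline = 500, df_baseline = 60,
            n = 200)
  idx <- fit_indices(f, n = 200)
  expect_equal(idx$cfi, 1)
  expect_equal(idx$rmsea, 0)
  # hand-computed tuple
  f2 <- list(chisq = 150, df = 50, chisq_baseline = 1000, df_baseline = 66,
             n = 1001)
  idx2 <- fit_indices(f2, n = 1001)
  expect_equal(idx2$cfi, 1 - 100 / 934, tolerance = 1e-12)
  expect_equal(idx2$rmsea, sqrt(100 / 50000), tolerance = 1e-12)
  expect_equal(idx2$tli,
               ((1000 / 66) - (150 / 50)) / ((1000 / 66) - 1),
               tolerance = 1e-12)
  # acceptability thresholds
  expect_true(fit_indices(list(chisq = 60, df = 50, chisq_baseline = 1000,
                               df_baseline = 66, n = 500))$acceptable)
  expect_false(fit_indices(list(chisq = 900, df = 50,
                                chisq_baseline = 1000, df_baseline = 66,
                                n = 500))$acceptable)
  expect_error(fit_indices(list(chisq = 1, df = 1, chisq_baseline = 1,
                                df_baseline = 0, n = 10)), "baseline")
})

test_that("fit indices agree with an independent recomputation", {
  # spreadsheet-style recomputation written as explicit steps
  set.seed(4)
  for (rep in 1:10) {
    df <- sample(10:80, 1); df0 <- df + sample(5:30, 1)
    chisq <- df * runif(1, 0.5, 4); chisq0 <- df0 * runif(1, 5, 20)
    n <- sample(200:3000, 1)
    idx <- fit_indices(list(chisq = chisq, df = df,
                            chisq_baseline = chisq0, df_baseline = df0,
                            n = n))
    d <- chisq - df
    d0 <- chisq0 - df0
    cfi_hand <- 1 - max(d, 0) / max(d, d0, 0)
    rat <- chisq0 / df0
    tli_hand <- (rat - chisq / df) / (rat - 1)
    rmsea_hand <- sqrt(max(d, 0) / (df * (n - 1)))
    expect_equal(idx$cfi, cfi_hand, tolerance = 1e-10)
    expect_equal(idx$tli, tli_hand, tolerance = 1e-10)
    expect_equal(idx$rmsea, rmsea_hand, tolerance = 1e-10)
  }
})

test_that("posterior predictive p-value is calibrated under the true model", {
  tr <- fast_truth(n = 600, seed = 5)
  dat <- fit_data_from(generate_dataset(tr))
  spec <- quantsem:::default_qsem_spec(
    mcmc = list(chains = 2L, iter = 2000L, burnin = 800L))
  fit <- gibbs_fit(dat, spec, tau = 0.5, seed = 2, store_latent = 600)
  ppc <- posterior_predictive_pvalue(fit, seed = 9)
  expect_gte(ppc$p_value, 0.3)
  expect_lte(ppc$p_value, 0.7)
  # two replicate-simulation seeds agree within the stated noise bound
  ppc2 <- posterior_predictive_pvalue(fit, seed = 1234)
  expect_lt(abs(ppc$p_value - ppc2$p_value), 0.05)
  # invariance to the order of retained draws
  fit_shuffled <- fit
  set.seed(3)
  perm <- sample(length(fit$latent))
  fit_shuffled$latent <- fit$latent[perm]
  ppc3 <- posterior_predictive_pvalue(fit_shuffled, seed = 9)
  expect_equal(sort(ppc3$d_obs), sort(ppc$d_obs), tolerance = 1e-12)
  expect_lt(abs(ppc3$p_value - ppc$p_value), 0.05)
  expect_error(posterior_predictive_pvalue(fit, min_draws = 10000),
               "at least")
})

test_that("suppressing a real latent association is detected", {
  tr <- synthetic_truth(n = 600, gamma = c(0.2, 1.5), seed = 6)
  dat <- fit_data_from(generate_dataset(tr))
  spec0 <- quantsem:::default_qsem_spec(
    mcmc = list(chains = 2L, iter = 2000L, burnin = 800L),
    gamma_fixed = c(0, 0))
  fit0 <- gibbs_fit(dat, spec0, tau = 0.5, seed = 2, store_latent = 600)
  ppc0 <- posterior_predictive_pvalue(fit0, seed = 9)
  expect_true(ppc0$p_value < 0.05 || ppc0$p_value > 0.95)
})
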