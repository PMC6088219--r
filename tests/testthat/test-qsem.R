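test_that("spec construction validates its contracts", {
  expect_error(qsem_spec("a", list(x = "b"), quantiles = c(0, 0.5)),
               "inside")
  expect_error(qsem_spec("a", list(x = "b"), gamma_fixed = c(0, 0)),
               "one entry per latent predictor")
  sp <- qsem_spec("a", list(x = "b"), quantiles = 0.3,
                  priors = list(coef_var = 25))
  expect_equal(sp$priors$coef_var, 25)
  expect_equal(sp$priors$loading_var, 100)
  expect_equal(sp$mcmc$iter, 6000L)
})

test_that("identical seed and configuration give identical draws", {
  tr <- fast_truth(n = 120, seed = 5)
  dat <- fit_data_from(generate_dataset(tr))
  spec <- quantsem:::default_qsem_spec(
    mcmc = list(chains = 2L, iter = 300L, burnin = 100L))
  f1 <- gibbs_fit(dat, spec, tau = 0.5, seed = 77, store_latent = 10)
  f2 <- gibbs_fit(dat, spec, tau = 0.5, seed = 77, store_latent = 10)
  expect_identical(f1$chains, f2$chains)
  f3 <- gibbs_fit(dat, spec, tau = 0.5, seed = 78, store_latent = 10)
  expect_false(identical(f1$chains[[1]], f3$chains[[1]]))
})

test_that("posterior summaries flag significance by the credible interval", {
  tr <- fast_truth(n = 500, seed = 6)
  dat <- fit_data_from(generate_dataset(tr))
  spec <- quantsem:::default_qsem_spec(mcmc = fast_mcmc)
  fit <- gibbs_fit(dat, spec, tau = 0.5, seed = 2, store_latent = 50)
  sm <- fit$summary
  expect_identical(sm$significant, sm$lower > 0 | sm$upper < 0)
  g <- sm[sm$parameter == "gamma_personal", ]
  expect_true(g$significant)        # strong true effect, must be detected
  expect_true(g$lower < g$median && g$median < g$upper)
  expect_true(all(sm$mean[grep("^psi_", sm$parameter)] > 0))
  expect_true(sm$mean[sm$parameter == "sigma"] > 0)
  # anchor loadings are not sampled; free loadings are near 1 (truth)
  expect_length(grep("^lambda_", sm$parameter), 11)
  expect_lt(max(abs(sm$mean[grep("^lambda_", sm$parameter)] - 1)), 0.25)
})

test_that("parameter recovery at the median on a moderate cohort", {
  tr <- fast_truth(n = 800, seed = 15)
  dat <- fit_data_from(generate_dataset(tr))
  spec <- quantsem:::default_qsem_spec(
    mcmc = list(chains = 2L, iter = 2000L, burnin = 800L))
  fit <- gibbs_fit(dat, spec, tau = 0.5, seed = 4, store_latent = 100)
  g <- fit$summary$mean[grep("^gamma_", fit$summary$parameter)]
  expect_lt(abs(g[1] - tr$gamma[1]), 0.15)
  expect_lt(abs(g[2] - tr$gamma[2]), 0.15)
  expect_lt(abs(residual_sign_fraction(fit)$sign_fraction - 0.5), 0.03)
})

test_that("null structural effects are covered by credible intervals", {
  spec <- quantsem:::default_qsem_spec(
    mcmc = list(chains = 1L, iter = 1500L, burnin = 500L))
  cover <- matrix(NA, 20, 2)
  for (r in 1:20) {
    tr <- synthetic_truth(n = 400, gamma = c(0, 0),
                          error = quantsem:::make_error("normal", sd = 0.6),
                          seed = 100 + r)
    dat <- fit_data_from(generate_dataset(tr))
    fit <- gibbs_fit(dat, spec, tau = 0.5, seed = r, store_latent = 10)
    sm <- fit$summary[grep("^gamma_", fit$summary$parameter), ]
    cover[r, ] <- sm$lower <= 0 & sm$upper >= 0
  }
  expect_gte(colMeans(cover)[1], 0.9)
  expect_gte(colMeans(cover)[2], 0.9)
})

test_that("a single requested quantile reproduces the single fit", {
  tr <- fast_truth(n = 150, seed = 8)
  dat <- fit_data_from(generate_dataset(tr))
  spec <- quantsem:::default_qsem_spec(
    quantiles = 0.5, mcmc = list(chains = 1L, iter = 400L, burnin = 150L))
  grid <- fit_all_quantiles(dat, spec, seed = 9, store_latent = 10)
  single <- gibbs_fit(dat, spec, tau = 0.5, seed = 9, store_latent = 10)
  expect_identical(grid$fits$tau_0.5$chains, single$chains)
  expect_setequal(unique(grid$table$tau), 0.5)
})

test_that("location-shift truth yields flat coefficient paths within bands", {
  # gamma constant over tau and symmetric errors: the true quantile
  # coefficients do not vary with tau
  tr <- synthetic_truth(n = 1200,
                        error = quantsem:::make_error("normal", sd = 0.6),
                        seed = 30)
  dat <- fit_data_from(generate_dataset(tr))
  spec <- quantsem:::default_qsem_spec(
    quantiles = c(0.25, 0.5, 0.75),
    mcmc = list(chains = 1L, iter = 2000L, burnin = 800L))
  grid <- fit_all_quantiles(dat, spec, seed = 13, store_latent = 20)
  for (par in c("gamma_socioeconomic", "gamma_personal")) {
    d <- grid$table[grid$table$parameter == par, ]
    expect_true(all(d$lower <= tr$gamma[[which(par == c(
      "gamma_socioeconomic", "gamma_personal"))]]))
    expect_true(all(d$upper >= tr$gamma[[which(par == c(
      "gamma_socioeconomic", "gamma_personal"))]]))
    # each tau's estimate inside every other tau's band
    expect_true(all(outer(d$mean, d$lower, ">=") &
                      outer(d$mean, d$upper, "<=")))
  }
})

test_that("predictor-driven error scale makes the coefficient grow in tau", {
  set.seed(9)
  n <- 1200
  tr <- fast_truth(n = n, seed = 77)
  sim <- generate_dataset(tr)
  xi <- as.matrix(sim$latent[, 2:3])
  set.seed(10)
  scale_i <- pmax(0.2, 1 + 0.8 * xi[, 2])
  eta <- as.numeric(sim$X %*% tr$b + xi %*% tr$gamma +
                      rnorm(n, 0, 0.5 * scale_i))
  om <- cbind(eta, xi)
  eps <- matrix(rnorm(n * 14), n, 14) %*% diag(sqrt(tr$Psi))
  Y <- sweep(om %*% t(tr$Lambda) + eps, 2, tr$mu, "+")
  colnames(Y) <- tr$indicator_names
  dat <- cbind(as.data.frame(Y), as.data.frame(sim$X))
  spec <- quantsem:::default_qsem_spec(
    mcmc = list(chains = 1L, iter = 2000L, burnin = 800L))
  gp <- vapply(c(0.1, 0.9), function(tau) {
    fit <- gibbs_fit(dat, spec, tau = tau, seed = 3, store_latent = 10)
    fit$summary$mean[fit$summary$parameter == "gamma_personal"]
  }, numeric(1))
  expect_gt(gp[2], gp[1] + 0.2)
})

test_that("latent snapshots are internal and never enter the model data", {
  tr <- fast_truth(n = 100, seed = 12)
  sim <- generate_dataset(tr)
  spec <- quantsem:::default_qsem_spec()
  md <- quantsem:::qsem_model_data(fit_data_from(sim), spec, TRUE)
  expect_false(any(c("eta", "xi_socioeconomic", "xi_personal") %in%
                     colnames(md$Y)))
  expect_identical(ncol(md$Y), 14L)
})
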