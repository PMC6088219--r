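# Shared fixture builders. Everything is generated in code at test time.

# small synthetic cohort with normal structural errors (fast default)
fast_truth <- function(n = 400, seed = 1, ...) {
  synthetic_truth(n = n, seed = seed, ...)
}

fast_mcmc <- list(chains = 2L, iter = 1500L, burnin = 600L, thin = 1L)

fit_data_from <- function(sim) {
  cbind(sim$indicators, as.data.frame(sim$X))
}

# degenerate-measurement dataset: every latent observed through two
# near-noiseless indicators, so the structural part is plain quantile
# regression on observables
degenerate_qr_data <- function(n = 200, tau = 0.5, sigma = 0.1,
                               noise_sd = 0.01, seed = 42) {
  set.seed(seed)
  X <- cbind(z1 = stats::rnorm(n), z2 = stats::rbinom(n, 1, 0.4))
  xi <- matrix(stats::rnorm(n * 2), n, 2) %*%
    chol(matrix(c(1, 0.3, 0.3, 1), 2))
  b_true <- c(0.5, -0.4); g_true <- c(0.3, 0.7)
  eta <- as.numeric(X %*% b_true + xi %*% g_true +
                      rald(n, ald_params(tau, sigma)))
  mknoise <- function(v) v + stats::rnorm(n, 0, noise_sd)
  dat <- data.frame(
    e1 = mknoise(eta), e2 = mknoise(eta),
    p1 = mknoise(xi[, 1]), p2 = mknoise(xi[, 1]),
    q1 = mknoise(xi[, 2]), q2 = mknoise(xi[, 2]),
    z1 = X[, 1], z2 = X[, 2]
  )
  list(data = dat, eta = eta, xi = xi, X = X,
       b_true = b_true, g_true = g_true)
}

degenerate_spec <- function(mcmc = list(chains = 2L, iter = 8000L,
                                        burnin = 3000L)) {
  qsem_spec(c("e1", "e2"),
            list(xi1 = c("p1", "p2"), xi2 = c("q1", "q2")),
            covariates = c("z1", "z2"), mcmc = mcmc)
}

# draws whose *sample* correlation matrix equals R exactly (whiten, then
# recolor); isolates closed-form identities from sampling noise
exact_cor_data <- function(n, R, seed = 1) {
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * ncol(R)), n)
  Z <- scale(Z, scale = FALSE)
  Z <- Z %*% solve(chol(stats::cov(Z)))
  Z %*% chol(R)
}

# brute-force exact quantile regression: enumerate every p-subset vertex
# (the LP basic solutions) and return the check-loss minimizer
brute_force_quantreg <- function(X, y, tau) {
  n <- nrow(X); p <- ncol(X)
  best_obj <- Inf; best <- NULL
  cmb <- utils::combn(n, p)
  for (j in seq_len(ncol(cmb))) {
    B <- cmb[, j]
    XB <- X[B, , drop = FALSE]
    if (abs(det(XB)) < 1e-10) next
    b <- solve(XB, y[B])
    obj <- sum(ald_check_loss(as.numeric(y - X %*% b), tau))
    if (obj < best_obj) { best_obj <- obj; best <- b }
  }
  list(coefficients = as.numeric(best), objective = best_obj)
}
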