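#' Maximum-likelihood (mean-regression) structural equation model
#'
#' The conventional comparator: the same measurement structure as the
#' quantile model, with a normal mean-zero structural error, estimated by
#' maximum likelihood. With indicator data and covariates, the full
#' conditional Gaussian likelihood of the indicators given covariates is
#' maximized by quasi-Newton iteration (BFGS) from moment-based starting
#' values; with a covariance matrix `S` (no covariates), the standard
#' discrepancy `F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p` is
#' minimized and `chisq = (n - 1) F_ML`. The baseline model for
#' incremental fit indices is the independence model with free variances.
#'
#' @param data Data frame with indicator and covariate columns, or `NULL`
#'   when `S` is supplied.
#' @param spec A [qsem_spec()]; its quantile levels are ignored here.
#' @param S Optional sample (or population) covariance of the indicators,
#'   ordered as `c(eta_indicators, unlist(xi_indicators))`.
#' @param n Sample size (required with `S`).
#' @param standardize z-score indicators first (data mode), default `TRUE`.
#' @return Object of class `classical_sem_fit`: `estimates` (named list
#'   with `Lambda`, `mu`, `Psi`, `gamma`, `b`, `Phi_xi`, `psi_delta`),
#'   `S`, `Sigma`, `F_ML`, `chisq`, `df`, `chisq_baseline`, `df_baseline`,
#'   `n`, `converged`, `heywood`.
#' @export
fit_mean_sem <- function(data = NULL, spec, S = NULL, n = NULL,
                         standardize = TRUE) {
  ind_cols <- c(spec$eta_indicators, unlist(spec$xi_indicators,
                                            use.names = FALSE))
  p <- length(ind_cols)
  nxi <- length(spec$xi_indicators)
  blocks <- c(list(spec$eta_indicators), spec$xi_indicators)
  factor_of <- integer(p); anchor <- integer(p)
  for (k in seq_along(blocks)) {
    idx <- match(blocks[[k]], ind_cols)
    factor_of[idx] <- k
    anchor[idx[1]] <- 1L
  }

  if (is.null(S)) {
    stopifnot(!is.null(data))
    md <- qsem_model_data(data, spec, standardize)
    Y <- md$Y; X <- md$X
    n <- nrow(Y); q <- ncol(X)
  } else {
    stopifnot(!is.null(n), nrow(S) == p)
    Y <- NULL; X <- matrix(0, 0, 0); q <- 0L
  }

  free_l <- which(anchor == 0L)
  n_l <- length(free_l)
  n_phi <- nxi * (nxi + 1) / 2

  # parameter vector: lambda_free, gamma, b, log psi (p), log psi_delta,
  # log-Cholesky of Phi_xi
  unpack <- function(th) {
    i <- 0
    lam <- rep(1, p)
    lam[free_l] <- th[i + seq_len(n_l)]; i <- i + n_l
    gam <- th[i + seq_len(nxi)]; i <- i + nxi
    b <- if (q > 0) th[i + seq_len(q)] else numeric(0); i <- i + q
    psi <- exp(th[i + seq_len(p)]); i <- i + p
    psd <- exp(th[i + 1]); i <- i + 1
    L <- matrix(0, nxi, nxi)
    L[lower.tri(L, diag = TRUE)] <- th[i + seq_len(n_phi)]
    diag(L) <- exp(diag(L))
    list(lambda = lam, gamma = gam, b = b, psi = psi, psi_delta = psd,
         Phi = L %*% t(L))
  }

  implied_cov <- function(par) {
    Phi_omega <- matrix(0, nxi + 1, nxi + 1)
    Phi_omega[-1, -1] <- par$Phi
    pg <- par$Phi %*% par$gamma
    Phi_omega[1, 1] <- sum(par$gamma * pg) + par$psi_delta
    Phi_omega[1, -1] <- pg
    Phi_omega[-1, 1] <- pg
    Lambda <- matrix(0, p, nxi + 1)
    Lambda[cbind(seq_len(p), factor_of)] <- par$lambda
    Lambda %*% Phi_omega %*% t(Lambda) + diag(par$psi)
  }

  if (is.null(S)) {
    # sufficient statistics of the conditional mean model
    ybar <- colMeans(Y); xbar <- colMeans(X)
    Yc <- sweep(Y, 2, ybar); Xc <- sweep(X, 2, xbar)
    Syy <- crossprod(Yc); Syx <- crossprod(Yc, Xc); Sxx <- crossprod(Xc)
    eta_rows <- which(factor_of == 1L)
    negll <- function(th) {
      par <- unpack(th)
      Sig <- implied_cov(par)
      ch <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      lcol <- numeric(p); lcol[eta_rows] <- par$lambda[eta_rows]
      Sbu <- Syx %*% par$b                 # sum (y - ybar)(u - ubar)
      suu <- as.numeric(t(par$b) %*% Sxx %*% par$b)
      RR <- Syy - tcrossprod(lcol, Sbu) - tcrossprod(Sbu, lcol) +
        tcrossprod(lcol) * suu
      ldet <- 2 * sum(log(diag(ch)))
      val <- n / 2 * ldet + 0.5 * sum(diag(chol2inv(ch) %*% RR))
      if (!is.finite(val)) 1e10 else val
    }
  } else {
    ldetS <- determinant(S, logarithm = TRUE)$modulus
    negll <- function(th) {
      par <- unpack(th)
      Sig <- implied_cov(par)
      ch <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      val <- 2 * sum(log(diag(ch))) + sum(diag(chol2inv(ch) %*% S)) -
        as.numeric(ldetS) - p
      if (!is.finite(val)) 1e10 else val
    }
  }

  th0 <- start_values(Y, X, S, spec, factor_of, free_l, n_l, nxi, q, n_phi)
  opt <- stats::optim(th0, negll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-12))
  # one restart helps escape flat starts
  opt2 <- stats::optim(opt$par, negll, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-14))
  if (opt2$value <= opt$value) opt <- opt2
  par <- unpack(opt$par)

  heywood <- any(par$psi < 1e-6) || par$psi_delta < 1e-6
  if (heywood) {
    warning("Heywood case: unique variance at boundary, clamped at 1e-6")
    par$psi <- pmax(par$psi, 1e-6)
    par$psi_delta <- max(par$psi_delta, 1e-6)
  }
  Sigma_hat <- implied_cov(par)

  n_free_cov <- n_l + nxi + p + 1 + n_phi  # covariance-side free parameters
  if (is.null(S)) {
    S_ml <- crossprod(sweep(Y, 2, colMeans(Y))) / (n - 1)
    # likelihood-ratio chi-square against the saturated conditional model
    XX <- cbind(1, X)
    Bhat <- qr.solve(XX, Y)
    Rsat <- Y - XX %*% Bhat
    Ssat <- crossprod(Rsat) / n
    # log-likelihoods with the common 2*pi constant dropped on both sides
    ll_mod <- -negll(opt$par)
    ll_sat <- -(n / 2 * as.numeric(determinant(Ssat, TRUE)$modulus) +
                  n * p / 2)
    chisq <- max(2 * (ll_sat - ll_mod), 0)
    df <- (p * (p + 1) / 2 + p * (q + 1)) - (n_free_cov + p + q)
    # baseline: independent indicators, free means and variances, no covariates
    v0 <- apply(Y, 2, function(y) mean((y - mean(y))^2))
    ll_0 <- -(n / 2 * sum(log(v0)) + n * p / 2)
    chisq0 <- max(2 * (ll_sat - ll_0), 0)
    df0 <- (p * (p + 1) / 2 + p * (q + 1)) - 2 * p
    F_ML <- chisq / (n - 1)
  } else {
    F_ML <- max(negll(opt$par), 0)
    chisq <- (n - 1) * F_ML
    df <- p * (p + 1) / 2 - n_free_cov
    F0 <- sum(log(diag(S))) - as.numeric(determinant(S, TRUE)$modulus)
    chisq0 <- (n - 1) * F0
    df0 <- p * (p - 1) / 2
    S_ml <- S
  }

  mu_hat <- if (is.null(S)) {
    lcol <- numeric(p); lcol[which(factor_of == 1L)] <-
      par$lambda[which(factor_of == 1L)]
    colMeans(Y) - lcol * mean(X %*% par$b)
  } else rep(NA_real_, p)

  Lambda_hat <- matrix(0, p, nxi + 1,
                       dimnames = list(ind_cols, c("eta",
                                                   names(spec$xi_indicators))))
  Lambda_hat[cbind(seq_len(p), factor_of)] <- par$lambda

  structure(list(
    estimates = list(Lambda = Lambda_hat, mu = mu_hat, Psi = par$psi,
                     gamma = stats::setNames(par$gamma,
                                             names(spec$xi_indicators)),
                     b = stats::setNames(par$b, spec$covariates[seq_len(q)]),
                     Phi_xi = par$Phi, psi_delta = par$psi_delta),
    S = S_ml, Sigma = Sigma_hat, F_ML = F_ML,
    chisq = as.numeric(chisq), df = df,
    chisq_baseline = as.numeric(chisq0), df_baseline = df0,
    n = n, converged = opt$convergence == 0,
    gradient_norm = NA_real_, heywood = heywood
  ), class = "classical_sem_fit")
}

start_values <- function(Y, X, S, spec, factor_of, free_l, n_l, nxi, q,
                         n_phi) {
  p <- length(factor_of)
  th <- numeric(n_l + nxi + q + p + 1 + n_phi)
  th[seq_len(n_l)] <- 1                       # loadings
  i <- n_l + nxi + q
  if (!is.null(Y)) {
    # moment-based starts from block-mean proxies (EFA-flavored)
    prox <- vapply(seq_len(max(factor_of)), function(k) {
      rowMeans(Y[, factor_of == k, drop = FALSE])
    }, numeric(nrow(Y)))
    fit <- stats::lm.fit(cbind(prox[, -1, drop = FALSE], X), prox[, 1])
    th[n_l + seq_len(nxi)] <- fit$coefficients[seq_len(nxi)] * 0.8
    if (q > 0) th[n_l + nxi + seq_len(q)] <-
        fit$coefficients[nxi + seq_len(q)] * 0.8
    th[i + seq_len(p)] <- log(pmax(apply(Y, 2, stats::var) * 0.4, 1e-3))
    i <- i + p
    th[i + 1] <- log(max(stats::var(fit$residuals), 1e-3)); i <- i + 1
    Vp <- stats::cov(prox[, -1, drop = FALSE]) * 0.8 + diag(1e-3, nxi)
    L <- t(chol(Vp))
    diag(L) <- log(diag(L))
    th[i + seq_len(n_phi)] <- L[lower.tri(L, diag = TRUE)]
  } else {
    th[i + seq_len(p)] <- log(pmax(diag(S) * 0.4, 1e-3))
    i <- i + p
    th[i + 1] <- log(max(mean(diag(S)) * 0.3, 1e-3)); i <- i + 1
    L <- diag(sqrt(rep(mean(diag(S)) * 0.3, nxi)))
    diag(L) <- log(diag(L))
    th[i + seq_len(n_phi)] <- L[lower.tri(L, diag = TRUE)]
  }
  th
}

#' Goodness-of-fit indices for a classical SEM fit
#'
#' `CFI = 1 - max(chisq - df, 0) / max(chisq - df, chisq0 - df0, 0)`,
#' `TLI = ((chisq0/df0) - (chisq/df)) / ((chisq0/df0) - 1)` and
#' `RMSEA = sqrt(max(chisq - df, 0) / (df (n - 1)))`. When `chisq <= df`,
#' CFI is 1 and RMSEA is 0. The acceptability flag applies the
#' conventional screening thresholds RMSEA < 0.10 and CFI, TLI > 0.8.
#'
#' @param fit A `classical_sem_fit`, or a list with `chisq`, `df`,
#'   `chisq_baseline`, `df_baseline`.
#' @param n Sample size; defaults to `fit$n`.
#' @return List with `cfi`, `tli`, `rmsea`, `acceptable`.
#' @export
fit_indices <- function(fit, n = fit$n) {
  chisq <- fit$chisq; df <- fit$df
  chisq0 <- fit$chisq_baseline; df0 <- fit$df_baseline
  if (is.null(df0) || df0 <= 0) {
    stop("baseline degrees of freedom must be positive", call. = FALSE)
  }
  if (df <= 0) stop("model degrees of freedom must be positive",
                    call. = FALSE)
  num <- max(chisq - df, 0)
  den <- max(chisq - df, chisq0 - df0, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- ((chisq0 / df0) - (chisq / df)) / ((chisq0 / df0) - 1)
  rmsea <- sqrt(num / (df * (n - 1)))
  list(cfi = cfi, tli = tli, rmsea = rmsea,
       acceptable = (rmsea < 0.10) && (cfi > 0.8) && (tli > 0.8))
}

#' Posterior predictive p-value for a fitted quantile SEM
#'
#' For each retained latent-state snapshot (with its matching parameter
#' draw), simulates a replicate dataset from the fitted model - latent
#' predictors from N(0, Phi), structural error from the asymmetric Laplace,
#' indicators from the normal measurement model - and compares a
#' discrepancy on replicated versus observed data. The p-value is the
#' proportion of draws where the replicate discrepancy is at least the
#' observed one; values near 0.5 indicate a plausible model.
#'
#' The default `"joint"` discrepancy adds (i) the likelihood-ratio
#' chi-square-type measure of the standardized measurement residuals,
#' `n * F_ML(S_r, Sigma(theta))` with `S_r` the covariance of the
#' indicator residuals around their model-implied conditional means and
#' `Sigma(theta)` the model-implied marginal covariance (the log-determinant
#' term makes this sensitive to covariance structure the model cannot
#' reproduce, e.g. a suppressed latent association), and (ii) twice the
#' structural check loss of the latent residuals divided by the ALD scale.
#' `"measurement"` and `"structural"` use one component only.
#'
#' @param fit A `qsem_fit` with stored latent snapshots.
#' @param discrepancy `"joint"` (default), `"measurement"` or
#'   `"structural"`.
#' @param seed Seed for replicate simulation.
#' @param min_draws Minimum retained snapshots required (default 500).
#' @return List of class `ppc_result`: `p_value`, `d_obs`, `d_rep`,
#'   `n_draws`, `n_skipped`, `discrepancy`.
#' @export
posterior_predictive_pvalue <- function(fit,
                                        discrepancy = c("joint",
                                                        "measurement",
                                                        "structural"),
                                        seed = 1L, min_draws = 500L) {
  stopifnot(inherits(fit, "qsem_fit"))
  discrepancy <- match.arg(discrepancy)
  if (length(fit$latent) < min_draws) {
    stop(sprintf("need at least %d retained latent snapshots, have %d",
                 min_draws, length(fit$latent)), call. = FALSE)
  }
  set.seed(seed)
  tau <- fit$tau
  k1 <- (1 - 2 * tau) / (tau * (1 - tau))
  k2sq <- 2 / (tau * (1 - tau))
  Y <- fit$Y; X <- fit$X
  n <- nrow(Y); p <- ncol(Y)
  factor_of <- fit$factor_of
  nxi <- max(factor_of) - 1L

  d_obs <- d_rep <- rep(NA_real_, length(fit$latent))
  for (t in seq_along(fit$latent)) {
    snap <- fit$latent[[t]]
    draw <- fit$chains[[snap$chain]][snap$row, ]
    prm <- draw_params(draw, fit$par_names, p, nxi, factor_of)
    Lambda <- matrix(0, p, nxi + 1)
    Lambda[cbind(seq_len(p), factor_of)] <- prm$lambda

    var_delta <- prm$sigma^2 * (k1^2 + k2sq)
    mean_delta <- k1 * prm$sigma
    Phi_omega <- matrix(0, nxi + 1, nxi + 1)
    Phi_omega[-1, -1] <- prm$Phi
    pg <- prm$Phi %*% prm$gamma
    Phi_omega[1, 1] <- sum(prm$gamma * pg) + var_delta
    Phi_omega[1, -1] <- pg; Phi_omega[-1, 1] <- pg
    Sig <- Lambda %*% Phi_omega %*% t(Lambda) + diag(prm$psi)
    chS <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(chS)) next
    xb <- as.numeric(X %*% prm$b)
    lcol <- Lambda[, 1]

    ldet_Sig <- 2 * sum(log(diag(chS)))
    Sig_inv <- chol2inv(chS)
    Dm <- function(Ymat) {
      M <- sweep(tcrossprod(xb + mean_delta, lcol), 2, prm$mu, "+")
      R <- Ymat - M
      Sr <- crossprod(R) / n
      ldet_Sr <- determinant(Sr, logarithm = TRUE)$modulus
      n * (ldet_Sig - as.numeric(ldet_Sr) + sum(Sig_inv * Sr) - p)
    }
    Ds <- function(omega) {
      delta <- omega[, 1] - xb -
        as.numeric(omega[, -1, drop = FALSE] %*% prm$gamma)
      2 * sum(ald_check_loss(delta, tau)) / prm$sigma
    }

    # replicate from the fitted model at this draw
    xi_rep <- matrix(stats::rnorm(n * nxi), n, nxi) %*% chol(prm$Phi)
    delta_rep <- rald(n, ald_params(tau, prm$sigma))
    eta_rep <- xb + as.numeric(xi_rep %*% prm$gamma) + delta_rep
    omega_rep <- cbind(eta_rep, xi_rep)
    Y_rep <- sweep(omega_rep %*% t(Lambda) +
                     matrix(stats::rnorm(n * p), n, p) %*%
                     diag(sqrt(prm$psi)), 2, prm$mu, "+")

    do_ <- dr_ <- 0
    if (discrepancy %in% c("joint", "measurement")) {
      do_ <- do_ + Dm(Y); dr_ <- dr_ + Dm(Y_rep)
    }
    if (discrepancy %in% c("joint", "structural")) {
      do_ <- do_ + Ds(snap$omega); dr_ <- dr_ + Ds(omega_rep)
    }
    d_obs[t] <- do_; d_rep[t] <- dr_
  }

  ok <- is.finite(d_obs) & is.finite(d_rep)
  if (mean(!ok) > 0.05) {
    stop(sprintf("%.1f%% of draws gave non-finite discrepancies",
                 100 * mean(!ok)), call. = FALSE)
  }
  structure(list(
    p_value = mean(d_rep[ok] >= d_obs[ok]),
    d_obs = d_obs[ok], d_rep = d_rep[ok],
    n_draws = sum(ok), n_skipped = sum(!ok),
    discrepancy = discrepancy
  ), class = "ppc_result")
}

# pull the structured parameters out of one named draw row
draw_params <- function(draw, par_names, p, nxi, factor_of) {
  nm <- par_names
  g <- draw[grep("^gamma_", nm)]
  b <- draw[grep("^b_", nm)]
  sigma <- draw[which(nm == "sigma")]
  lam <- rep(1, p)
  free <- grep("^lambda_", nm)
  # free loadings appear in indicator order among non-anchors
  lam_free_names <- sub("^lambda_", "", nm[free])
  mu <- draw[grep("^mu_", nm)]
  ind_names <- sub("^mu_", "", nm[grep("^mu_", nm)])
  lam[match(lam_free_names, ind_names)] <- draw[free]
  psi <- draw[grep("^psi_", nm)]
  phiv <- draw[grep("^phi_", nm)]
  Phi <- matrix(0, nxi, nxi)
  Phi[lower.tri(Phi, diag = TRUE)] <- phiv
  Phi <- Phi + t(Phi) - diag(diag(Phi))
  list(gamma = as.numeric(g), b = as.numeric(b), sigma = as.numeric(sigma),
       lambda = lam, mu = as.numeric(mu), psi = as.numeric(psi), Phi = Phi)
}
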