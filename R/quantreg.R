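#' Exact linear quantile regression by check-loss minimization
#'
#' Minimizes `sum_i rho_tau(y_i - x_i' beta)` exactly. The check loss is a
#' piecewise-linear convex function whose minimizers include a vertex of
#' the associated linear program, i.e. a coefficient vector that
#' interpolates `p` observations. The solver first runs a smoothed-loss
#' continuation (a softplus smoothing of the check loss with decreasing
#' bandwidth, warm-started BFGS) to locate the optimum region, then
#' enumerates candidate interpolation bases among the smallest residuals
#' and returns the first basis whose LP dual multipliers are feasible:
#' solving `X_B' psi_B = -sum_{i not in B} psi_tau(r_i) x_i` must give
#' `psi_B` inside the box `[tau - 1, tau]`, the exact optimality
#' certificate for this problem.
#'
#' @param X Numeric design matrix (n x p, full column rank), including an
#'   intercept column if one is wanted.
#' @param y Numeric response vector.
#' @param tau Quantile level in (0, 1).
#' @return List: `coefficients`, `tau`, `objective`, `basis` (row indices
#'   interpolated), `dual` (the basis multipliers), `certified` (logical;
#'   `TRUE` means the dual feasibility certificate held exactly).
#' @export
fit_quantreg <- function(X, y, tau) {
  check_tau(tau)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n > p)

  beta <- qr.solve(X, y)
  scale0 <- max(stats::mad(y - X %*% beta), 1e-3)
  for (h in scale0 * 10^seq(-1, -8)) {
    beta <- stats::optim(
      beta,
      fn = function(b) sum(smooth_check(y - X %*% b, tau, h)),
      gr = function(b) -crossprod(X, smooth_check_grad(y - X %*% b, tau, h)),
      method = "BFGS",
      control = list(maxit = 500, reltol = 1e-14)
    )$par
  }

  r <- as.numeric(y - X %*% beta)
  ord <- order(abs(r))
  pool <- ord[seq_len(min(n, p + 6L))]
  cand <- utils::combn(pool, p)
  # try candidate bases nearest the continuation solution first
  cand <- cand[, order(colSums(matrix(match(cand, pool), nrow = p))),
               drop = FALSE]

  best <- list(coefficients = beta, objective = qr_objective(X, y, beta, tau),
               basis = integer(0), dual = numeric(0), certified = FALSE)
  for (j in seq_len(ncol(cand))) {
    B <- cand[, j]
    XB <- X[B, , drop = FALSE]
    if (abs(det(XB)) < 1e-10) next
    bB <- try(solve(XB, y[B]), silent = TRUE)
    if (inherits(bB, "try-error")) next
    rB <- as.numeric(y - X %*% bB)
    out <- setdiff(seq_len(n), B)
    g <- -colSums(X[out, , drop = FALSE] *
                    (tau - (rB[out] < 0)))
    psiB <- try(solve(t(XB), g), silent = TRUE)
    if (inherits(psiB, "try-error")) next
    if (all(psiB >= tau - 1 - 1e-9) && all(psiB <= tau + 1e-9)) {
      return(list(coefficients = as.numeric(bB), tau = tau,
                  objective = qr_objective(X, y, bB, tau),
                  basis = sort(B), dual = as.numeric(psiB),
                  certified = TRUE))
    }
    obj <- qr_objective(X, y, bB, tau)
    if (obj < best$objective) {
      best <- list(coefficients = as.numeric(bB), objective = obj,
                   basis = sort(B), dual = as.numeric(psiB),
                   certified = FALSE)
    }
  }
  warning("no dual-feasible basis found; returning best candidate")
  c(best[c("coefficients")], list(tau = tau), best[-1])
}

qr_objective <- function(X, y, beta, tau) {
  sum(ald_check_loss(as.numeric(y - X %*% beta), tau))
}

# softplus smoothing of rho_tau(u) = tau*u + max(-u, 0)
smooth_check <- function(u, tau, h) {
  tau * u + h * log1p(exp(-abs(u) / h)) + pmax(-u, 0)
}

# derivative wrt u; optim gr needs d loss / d beta = -X' this
smooth_check_grad <- function(u, tau, h) {
  tau - 1 / (1 + exp(u / h))
}
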