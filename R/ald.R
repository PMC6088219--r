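#' Quantile-regression check loss
#'
#' `rho_tau(u) = u * (tau - 1[u < 0])`, the piecewise-linear loss whose
#' minimizer over a conditional distribution is its `tau`-th quantile.
#' Convex in `u` with minimum 0 at `u = 0`.
#'
#' @param u Numeric vector of residuals.
#' @param tau Quantile level in (0, 1).
#' @return Nonnegative numeric vector.
#' @export
ald_check_loss <- function(u, tau) {
  check_tau(tau)
  u * (tau - (u < 0))
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau <= 0 || tau >= 1) {
    stop("tau must be a single number strictly inside (0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Asymmetric-Laplace augmentation constants
#'
#' The mixture representation `u = k1 * e + k2 * sqrt(sigma * e) * z`, with
#' `e` exponential with mean `sigma` and `z` standard normal, reproduces the
#' asymmetric Laplace distribution when `k1 = (1 - 2 tau) / (tau (1 - tau))`
#' and `k2^2 = 2 / (tau (1 - tau))`. `k1 = 0` iff `tau = 0.5`; `k2^2 >= 8`
#' with equality iff `tau = 0.5`.
#'
#' @param tau Quantile level in (0, 1).
#' @param sigma Positive scale.
#' @return List with `tau`, `sigma`, `k1`, `k2sq`.
#' @export
ald_params <- function(tau, sigma = 1) {
  check_tau(tau)
  if (!is.numeric(sigma) || length(sigma) != 1L || !isTRUE(sigma > 0)) {
    stop("sigma must be a positive scalar", call. = FALSE)
  }
  list(tau = tau, sigma = sigma,
       k1 = (1 - 2 * tau) / (tau * (1 - tau)),
       k2sq = 2 / (tau * (1 - tau)))
}

#' Asymmetric Laplace density
#'
#' `f(u) = tau (1 - tau) / sigma * exp(-rho_tau(u) / sigma)`: the working
#' likelihood under which the posterior mode of a regression corresponds to
#' the `tau`-th conditional quantile. The density integrates to 1 and its
#' `tau`-quantile is 0.
#'
#' @param u Numeric vector of evaluation points.
#' @param params List from [ald_params()].
#' @return Positive numeric vector of densities.
#' @export
ald_density <- function(u, params) {
  tau <- params$tau; sigma <- params$sigma
  check_tau(tau)
  tau * (1 - tau) / sigma * exp(-ald_check_loss(u, tau) / sigma)
}

#' Asymmetric Laplace density via its normal-exponential mixture
#'
#' Evaluates `integral N(u | k1 e, k2^2 sigma e) Exp(e | mean sigma) de` by
#' adaptive quadrature. This is the representation that makes the Gibbs
#' conditionals of the quantile structural model tractable; it must agree
#' with [ald_density()] to high accuracy, which the test suite checks.
#'
#' @param u Numeric vector of evaluation points.
#' @param params List from [ald_params()].
#' @param n_grid Quadrature subdivision limit, at least 100.
#' @return Positive numeric vector of densities.
#' @export
ald_mixture_density <- function(u, params, n_grid = 1000L) {
  tau <- params$tau; sigma <- params$sigma
  check_tau(tau)
  if (n_grid < 100L) stop("n_grid must be at least 100", call. = FALSE)
  k1 <- params$k1; k2sq <- params$k2sq
  one <- function(ui) {
    f <- function(e) {
      stats::dnorm(ui, mean = k1 * e, sd = sqrt(k2sq * sigma * e)) *
        stats::dexp(e, rate = 1 / sigma)
    }
    r <- stats::integrate(f, 0, Inf, subdivisions = n_grid,
                          rel.tol = 1e-10, abs.tol = 1e-12)
    if (r$message != "OK") stop("quadrature did not converge: ", r$message,
                                call. = FALSE)
    r$value
  }
  vapply(u, one, numeric(1))
}

#' Random draws from the asymmetric Laplace distribution
#'
#' Simulates via the normal-exponential mixture, so draws are exactly
#' ALD-distributed with `tau`-quantile 0 and scale `sigma`.
#'
#' @param n Number of draws.
#' @param params List from [ald_params()].
#' @return Numeric vector of length `n`.
#' @export
rald <- function(n, params) {
  e <- stats::rexp(n, rate = 1 / params$sigma)
  params$k1 * e + sqrt(params$k2sq * params$sigma * e) * stats::rnorm(n)
}

# mean, variance and moment skewness of ALD(0, sigma, tau); used for
# generator calibration and skewness targeting
ald_moments <- function(tau, sigma = 1) {
  p <- ald_params(tau, sigma)
  k1 <- p$k1; k2sq <- p$k2sq
  m <- k1 * sigma
  v <- sigma^2 * (k1^2 + k2sq)
  m3 <- sigma^3 * (2 * k1^3 + 3 * k1 * k2sq)
  list(mean = m, var = v, skewness = m3 / v^1.5)
}
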