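// Gibbs sampler for the Bayesian quantile structural equation model.
//
// Measurement: y_ij = mu_j + lambda_j * omega_{i, f(j)} + eps_ij,
//              eps_ij ~ N(0, psi_j), anchor loadings fixed at 1.
// Structural:  eta_i = x_i' b + gamma' xi_i + delta_i with
//              delta_i ~ ALD(0, sigma, tau), represented as
//              delta = k1 e + sqrt(k2sq sigma e) z, e ~ Exp(mean sigma).
// Latent predictors: xi_i ~ N(0, Phi).
//
// All full conditionals are conjugate under this augmentation; the mixing
// variable e_i has a GIG(1/2, chi_i, zeta) conditional, sampled exactly via
// the reciprocal inverse-Gaussian representation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double rinvgauss1(double mu, double lambda) {
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-300;
  double u = unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// GIG(lambda = 1/2, chi, zeta): density propto x^{-1/2} exp(-(chi/x + zeta x)/2)
static double rgig_half(double chi, double zeta) {
  if (chi < 1e-14) {
    // degenerates to Gamma(3/2, rate = zeta/2)
    return R::rgamma(1.5, 2.0 / zeta);
  }
  double ig = rinvgauss1(std::sqrt(zeta / chi), zeta);
  return 1.0 / ig;
}

// draw from N(P^{-1} rhs, P^{-1}) given precision P (small, SPD);
// P is symmetrized first: accumulated rank-one updates with widely varying
// weights can leave it asymmetric at floating-point level
static vec mvn_prec(const mat& P_raw, const vec& rhs) {
  mat P = symmatu(P_raw);
  mat U = chol(P);  // upper: P = U' U
  vec m = solve(trimatl(U.t()), rhs);
  m = solve(trimatu(U), m);
  vec z(P.n_rows);
  for (uword k = 0; k < z.n_elem; ++k) z(k) = norm_rand();
  return m + solve(trimatu(U), z);
}

// Phi ~ InverseWishart(A, nu) via Bartlett on Phi^{-1} ~ Wishart(A^{-1}, nu)
static mat riwish(const mat& A_raw, double nu) {
  mat A = symmatu(A_raw);
  mat L = chol(inv_sympd(A), "lower");
  uword d = A.n_rows;
  mat T(d, d, fill::zeros);
  for (uword i = 0; i < d; ++i) {
    T(i, i) = std::sqrt(R::rchisq(nu - (double)i));
    for (uword j = 0; j < i; ++j) T(i, j) = norm_rand();
  }
  mat W = L * T;
  W = W * W.t();
  return inv_sympd(W);
}

// [[Rcpp::export]]
Rcpp::List gibbs_qsem_cpp(const arma::mat& Y, const arma::mat& X,
                          const arma::ivec& factor_of,
                          const arma::ivec& anchor,
                          double tau, const Rcpp::List& priors,
                          int n_iter, int n_burn, int thin,
                          Rcpp::Nullable<Rcpp::NumericVector> gamma_fixed,
                          int store_latent) {
  const uword n = Y.n_rows, p = Y.n_cols, q = X.n_cols;
  const uword nfac = (uword)factor_of.max();
  const uword nxi = nfac - 1;

  const double k1 = (1.0 - 2.0 * tau) / (tau * (1.0 - tau));
  const double k2sq = 2.0 / (tau * (1.0 - tau));

  const double load_var = Rcpp::as<double>(priors["loading_var"]);
  const double coef_var = Rcpp::as<double>(priors["coef_var"]);
  const double psi_a = Rcpp::as<double>(priors["psi_a"]);
  const double psi_b = Rcpp::as<double>(priors["psi_b"]);
  const double sig_a = Rcpp::as<double>(priors["sigma_a"]);
  const double sig_b = Rcpp::as<double>(priors["sigma_b"]);
  const mat phi_S = Rcpp::as<mat>(priors["phi_S"]);
  const double phi_df = Rcpp::as<double>(priors["phi_df"]);

  const bool gfix = gamma_fixed.isNotNull();
  vec gamma(nxi, fill::zeros);
  if (gfix) gamma = Rcpp::as<vec>(gamma_fixed.get());

  // state
  rowvec mu = mean(Y, 0);
  vec lambda(p, fill::ones);
  vec psi = vectorise(var(Y, 0, 0)) * 0.5;
  psi.transform([](double v) { return std::max(v, 1e-4); });
  vec b(q, fill::zeros);
  double sigma = 1.0;
  mat Phi = eye(nxi, nxi);
  vec e(n, fill::ones);
  e *= sigma;

  // init latent states from block means of centered indicators
  mat omega(n, nfac, fill::zeros);
  {
    mat Yc = Y.each_row() - mu;
    for (uword k = 0; k < nfac; ++k) {
      uvec blk = find(factor_of == (sword)(k + 1));
      omega.col(k) = mean(Yc.cols(blk), 1);
    }
  }

  const int n_keep = (n_iter - n_burn) / thin;
  const uword npar = nxi + q + 1 + (p - (uword)accu(anchor)) + p + p +
    nxi * (nxi + 1) / 2;
  mat draws((uword)n_keep, npar, fill::zeros);

  const int n_store = std::min(store_latent, n_keep);
  cube omega_store(n, nfac, (uword)std::max(n_store, 0));
  mat e_store(n, (uword)std::max(n_store, 0));
  ivec store_rows(std::max(n_store, 0));
  // kept-iteration indices at which latent states are snapshotted
  std::vector<int> store_at;
  if (n_store > 0) {
    for (int s = 0; s < n_store; ++s)
      store_at.push_back((int)std::floor((s + 1.0) * n_keep / n_store) - 1);
  }

  int kept = 0, stored = 0;
  vec vload(nfac);  // structural direction (1, -gamma)

  for (int it = 0; it < n_iter; ++it) {
    // --- structural residuals and mixing variables e_i ---
    vec delta = omega.col(0) - X * b;
    if (nxi > 0) delta -= omega.cols(1, nfac - 1) * gamma;
    const double zeta = 2.0 / sigma + k1 * k1 / (k2sq * sigma);
    for (uword i = 0; i < n; ++i) {
      double chi = delta(i) * delta(i) / (k2sq * sigma);
      e(i) = std::max(rgig_half(chi, zeta), 1e-12);
    }

    // --- latent states omega_i ---
    mat Phi_inv = inv_sympd(symmatu(Phi));
    vec m_diag(nfac, fill::zeros);
    mat W(p, nfac, fill::zeros);
    for (uword j = 0; j < p; ++j) {
      uword f = (uword)factor_of(j) - 1;
      m_diag(f) += lambda(j) * lambda(j) / psi(j);
      W(j, f) = lambda(j) / psi(j);
    }
    mat P0 = diagmat(m_diag);
    P0.submat(1, 1, nfac - 1, nfac - 1) += Phi_inv;
    vload(0) = 1.0;
    for (uword k = 0; k < nxi; ++k) vload(k + 1) = -gamma(k);
    mat T = (Y.each_row() - mu) * W;  // n x nfac
    vec xb = X * b;
    for (uword i = 0; i < n; ++i) {
      double wi = 1.0 / (k2sq * sigma * e(i));
      double ai = xb(i) + k1 * e(i);
      mat P = P0 + wi * (vload * vload.t());
      vec rhs = T.row(i).t() + (wi * ai) * vload;
      omega.row(i) = mvn_prec(P, rhs).t();
    }

    // --- measurement intercepts and loadings ---
    for (uword j = 0; j < p; ++j) {
      uword f = (uword)factor_of(j) - 1;
      vec w = omega.col(f);
      vec yj = Y.col(j);
      if (anchor(j)) {
        vec r = yj - w;
        double prec = n / psi(j) + 1.0 / load_var;
        double mean_ = accu(r) / psi(j) / prec;
        mu(j) = mean_ + norm_rand() / std::sqrt(prec);
      } else {
        mat P(2, 2);
        double Sw = accu(w), Sww = dot(w, w);
        P(0, 0) = n / psi(j);  P(0, 1) = Sw / psi(j);
        P(1, 0) = P(0, 1);     P(1, 1) = Sww / psi(j);
        P(0, 0) += 1.0 / load_var; P(1, 1) += 1.0 / load_var;
        vec rhs(2);
        rhs(0) = accu(yj) / psi(j);
        rhs(1) = dot(w, yj) / psi(j);
        vec par = mvn_prec(P, rhs);
        mu(j) = par(0);
        lambda(j) = par(1);
      }
    }

    // --- unique variances ---
    for (uword j = 0; j < p; ++j) {
      uword f = (uword)factor_of(j) - 1;
      vec r = Y.col(j) - mu(j) - lambda(j) * omega.col(f);
      double rate = psi_b + 0.5 * dot(r, r);
      psi(j) = std::max(1.0 / R::rgamma(psi_a + 0.5 * n, 1.0 / rate), 1e-12);
    }

    // --- structural coefficients (gamma, b) ---
    {
      vec wts(n);
      for (uword i = 0; i < n; ++i) wts(i) = 1.0 / (k2sq * sigma * e(i));
      vec target = omega.col(0) - k1 * e;
      if (gfix) {
        if (nxi > 0) target -= omega.cols(1, nfac - 1) * gamma;
        if (q > 0) {
          mat Xw = X.each_col() % wts;
          mat P = X.t() * Xw;
          P.diag() += 1.0 / coef_var;
          vec rhs = Xw.t() * target;
          b = mvn_prec(P, rhs);
        }
      } else {
        mat Z(n, nxi + q);
        if (nxi > 0) Z.cols(0, nxi - 1) = omega.cols(1, nfac - 1);
        if (q > 0) Z.cols(nxi, nxi + q - 1) = X;
        mat Zw = Z.each_col() % wts;
        mat P = Z.t() * Zw;
        P.diag() += 1.0 / coef_var;
        vec rhs = Zw.t() * target;
        vec par = mvn_prec(P, rhs);
        gamma = par.subvec(0, nxi - 1);
        if (q > 0) b = par.subvec(nxi, nxi + q - 1);
      }
    }

    // --- ALD scale sigma ---
    {
      vec delta2 = omega.col(0) - X * b;
      if (nxi > 0) delta2 -= omega.cols(1, nfac - 1) * gamma;
      double rate = sig_b + accu(e);
      for (uword i = 0; i < n; ++i) {
        double d = delta2(i) - k1 * e(i);
        rate += d * d / (2.0 * k2sq * e(i));
      }
      sigma = 1.0 / R::rgamma(sig_a + 1.5 * n, 1.0 / rate);
      if (!std::isfinite(sigma) || sigma < 1e-12) sigma = 1e-12;
    }

    // --- latent-predictor covariance ---
    if (nxi > 0) {
      mat Xi = omega.cols(1, nfac - 1);
      mat A = phi_S + Xi.t() * Xi;
      Phi = riwish(A, phi_df + (double)n);
    }

    if (!omega.is_finite() || !std::isfinite(sigma)) {
      Rcpp::stop("divergent chain: non-finite draw at iteration %d", it + 1);
    }

    // --- store ---
    if (it >= n_burn && (it - n_burn) % thin == 0) {
      uword c = 0;
      rowvec row(npar);
      for (uword k = 0; k < nxi; ++k) row(c++) = gamma(k);
      for (uword k = 0; k < q; ++k) row(c++) = b(k);
      row(c++) = sigma;
      for (uword j = 0; j < p; ++j) if (!anchor(j)) row(c++) = lambda(j);
      for (uword j = 0; j < p; ++j) row(c++) = mu(j);
      for (uword j = 0; j < p; ++j) row(c++) = psi(j);
      for (uword a = 0; a < nxi; ++a)
        for (uword bidx = a; bidx < nxi; ++bidx) row(c++) = Phi(bidx, a);
      draws.row((uword)kept) = row;

      if (stored < n_store && kept == store_at[(size_t)stored]) {
        omega_store.slice((uword)stored) = omega;
        e_store.col((uword)stored) = e;
        store_rows(stored) = kept;
        ++stored;
      }
      ++kept;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("draws") = draws,
    Rcpp::Named("omega_store") = omega_store,
    Rcpp::Named("e_store") = e_store,
    Rcpp::Named("store_rows") = store_rows.head(stored)
  );
}
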