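// Gibbs sampler for multi-kernel linear mixed models, sampling each
// random effect in its kernel's eigenbasis. Masked responses are handled
// by data augmentation (redrawn from their conditional each sweep).
// RNG comes from R's generator, so set.seed() in R makes runs
// deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List gibbs_kernel_cpp(arma::vec y, arma::uvec miss, arma::mat X,
                      List U, List d,
                      int burn, int niter, int thin,
                      double nu, arma::vec S, double S_e,
                      arma::vec fixed, arma::vec init_sig, double init_sige,
                      bool fix_resid) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int K = U.size();

  std::vector<arma::mat> Us(K);
  std::vector<arma::vec> ds(K), alphas(K), us(K);
  for (int k = 0; k < K; ++k) {
    Us[k] = as<arma::mat>(U[k]);
    ds[k] = as<arma::vec>(d[k]);
    alphas[k] = arma::zeros<arma::vec>(ds[k].n_elem);
    us[k] = arma::zeros<arma::vec>(n);
  }
  arma::vec sig = init_sig;
  double sige = init_sige;

  // flat-prior fixed effects: precompute (X'X)^{-1} and its Cholesky
  arma::mat XtX = X.t() * X;
  arma::mat Cxx = arma::inv_sympd(XtX);
  arma::mat Lxx = arma::chol(Cxx, "lower");

  arma::vec ycur = y;
  double ymean = 0.0;
  {
    double s = 0.0; int m = 0;
    arma::uvec ismiss = arma::zeros<arma::uvec>(n);
    for (unsigned int i = 0; i < miss.n_elem; ++i) ismiss[miss[i]] = 1;
    for (int i = 0; i < n; ++i) if (!ismiss[i]) { s += y[i]; ++m; }
    ymean = m > 0 ? s / m : 0.0;
  }
  for (unsigned int i = 0; i < miss.n_elem; ++i) ycur[miss[i]] = ymean;

  arma::vec beta = arma::zeros<arma::vec>(p);
  arma::vec e = ycur;  // residual given all-zero effects

  int nkeep = 0;
  for (int t = burn; t < niter; t += thin) ++nkeep;
  arma::mat sig_chain(nkeep, K + 1);
  arma::vec fitted_sum = arma::zeros<arma::vec>(n);
  arma::vec beta_sum = arma::zeros<arma::vec>(p);
  std::vector<arma::vec> u_sum(K, arma::zeros<arma::vec>(n));

  RNGScope scope;
  int kept = 0;
  for (int t = 0; t < niter; ++t) {
    // fixed effects
    arma::vec rb = e + X * beta;
    arma::vec bhat = Cxx * (X.t() * rb);
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z[j] = R::rnorm(0.0, 1.0);
    beta = bhat + std::sqrt(sige) * (Lxx * z);
    e = rb - X * beta;

    // random effects per kernel, in the eigenbasis
    for (int k = 0; k < K; ++k) {
      arma::vec r = e + us[k];
      arma::vec tk = Us[k].t() * r;
      arma::vec &a = alphas[k];
      const arma::vec &dk = ds[k];
      for (unsigned int j = 0; j < dk.n_elem; ++j) {
        double lam = sig[k] * dk[j];
        double denom = lam + sige;
        if (denom <= 0.0 || lam <= 0.0) { a[j] = 0.0; continue; }
        double v = lam * sige / denom;
        double m = lam / denom * tk[j];
        a[j] = m + R::rnorm(0.0, 1.0) * std::sqrt(v);
      }
      us[k] = Us[k] * a;
      e = r - us[k];
    }

    // kernel variances (scaled inverse chi-squared)
    for (int k = 0; k < K; ++k) {
      if (fixed[k] > 0.5) continue;
      double ss = 0.0;
      for (unsigned int j = 0; j < ds[k].n_elem; ++j) {
        if (ds[k][j] > 0) ss += alphas[k][j] * alphas[k][j] / ds[k][j];
      }
      sig[k] = (ss + nu * S[k]) / R::rchisq(nu + ds[k].n_elem);
    }
    if (!fix_resid) {
      double ss = arma::dot(e, e);
      sige = (ss + nu * S_e) / R::rchisq(nu + n);
    }

    // data augmentation for masked responses
    for (unsigned int i = 0; i < miss.n_elem; ++i) {
      int ix = miss[i];
      double fit = ycur[ix] - e[ix];
      double noise = R::rnorm(0.0, 1.0) * std::sqrt(sige);
      ycur[ix] = fit + noise;
      e[ix] = noise;
    }

    if (t >= burn && (t - burn) % thin == 0) {
      arma::vec fitted = ycur - e;
      fitted_sum += fitted;
      beta_sum += beta;
      for (int k = 0; k < K; ++k) {
        u_sum[k] += us[k];
        sig_chain(kept, k) = sig[k];
      }
      sig_chain(kept, K) = sige;
      ++kept;
    }
  }

  List u_mean(K);
  for (int k = 0; k < K; ++k) u_mean[k] = u_sum[k] / kept;
  return List::create(
    _["sigma_chain"] = sig_chain,
    _["beta_mean"] = beta_sum / kept,
    _["u_mean"] = u_mean,
    _["fitted_mean"] = fitted_sum / kept,
    _["n_kept"] = kept
  );
}
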