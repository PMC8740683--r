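#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mean-field coordinate-ascent variational inference for the spike-and-slab
// effect-size prior under the summary-statistics likelihood
//   betahat | beta ~ N(S R S^{-1} beta, S R S),  S = diag(se).
// In the natural parameterization the log-likelihood is, up to constTerm,
//   -0.5 beta' H beta + beta' b  with  H = S^{-1} R S^{-1}, b = betahat/se^2.
// Each beta_j has variational posterior alpha_j N(mu_j, svar_j) + (1-alpha_j) d0.
// SNPs with sigma2_j = 0 have a degenerate slab (beta_j = 0): they are held
// out of the updates and contribute nothing to likelihood or KL.
// [[Rcpp::export]]
List rssVarbvsFit(const NumericMatrix& H, const NumericVector& b,
                  const NumericVector& pi, const NumericVector& sigma2,
                  const IntegerVector& order, double constTerm,
                  double tol, int maxit) {
  const int p = b.size();
  NumericVector alpha(p), mu(p), svar(p), h(p), Hm(p);
  std::vector<bool> active(p);
  for (int j = 0; j < p; ++j) {
    h[j] = H(j, j);
    active[j] = sigma2[j] > 0.0;
    svar[j] = active[j] ? sigma2[j] / (1.0 + sigma2[j] * h[j]) : 0.0;
    alpha[j] = 0.0;
    mu[j] = 0.0;
  }
  std::vector<double> elbo;
  elbo.reserve(maxit);
  bool monotone = true, converged = false;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    for (int k = 0; k < p; ++k) {
      const int j = order[k];
      if (!active[j]) continue;
      const double mold = alpha[j] * mu[j];
      const double rj = b[j] - (Hm[j] - h[j] * mold);
      mu[j] = svar[j] * rj;
      double lo = std::log(pi[j] / (1.0 - pi[j]))
        + 0.5 * std::log(svar[j] / sigma2[j])
        + mu[j] * mu[j] / (2.0 * svar[j]);
      if (lo > 700.0) lo = 700.0;
      alpha[j] = 1.0 / (1.0 + std::exp(-lo));
      const double d = alpha[j] * mu[j] - mold;
      if (d != 0.0)
        for (int i = 0; i < p; ++i) Hm[i] += H(i, j) * d;
    }
    // refresh Hm from scratch once per sweep to stop incremental drift
    for (int i = 0; i < p; ++i) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += H(i, j) * alpha[j] * mu[j];
      Hm[i] = s;
    }
    double lin = 0.0, quad = 0.0, diagc = 0.0, kl = 0.0;
    for (int j = 0; j < p; ++j) {
      const double m = alpha[j] * mu[j];
      lin += b[j] * m;
      quad += m * Hm[j];
      if (!active[j]) continue;
      const double Eb2 = alpha[j] * (mu[j] * mu[j] + svar[j]);
      diagc += h[j] * (Eb2 - m * m);
      const double a = alpha[j];
      if (a > 0.0) kl += a * std::log(a / pi[j]);
      if (a < 1.0) kl += (1.0 - a) * std::log((1.0 - a) / (1.0 - pi[j]));
      kl -= 0.5 * a * (1.0 + std::log(svar[j] / sigma2[j])
                       - (svar[j] + mu[j] * mu[j]) / sigma2[j]);
    }
    const double e = constTerm + lin - 0.5 * (quad + diagc) - kl;
    if (!elbo.empty() && e < elbo.back() - 1e-8) monotone = false;
    const double prev = elbo.empty() ? R_NegInf : elbo.back();
    elbo.push_back(e);
    if (it > 1 && std::fabs(e - prev) < tol * (1.0 + std::fabs(e))) {
      converged = true;
      break;
    }
  }
  // SNPs with a degenerate slab keep their prior inclusion probability
  for (int j = 0; j < p; ++j)
    if (!active[j]) alpha[j] = pi[j];
  return List::create(_["alpha"] = alpha, _["mu"] = mu, _["svar"] = svar,
                      _["elbo"] = wrap(elbo),
                      _["logml"] = elbo.back(),
                      _["converged"] = converged,
                      _["monotone"] = monotone,
                      _["niter"] = (int)elbo.size());
}
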