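#include <Rcpp.h>
using namespace Rcpp;

// Blocked Gibbs sweep for the truncated Dirichlet-process latent-class
// capture-recapture model. Mirrors the R reference implementation
// (lcmcr_gibbs_r); uses R's RNG so runs are reproducible under set.seed().
//
// counts: observed cell counts (length P, all-zero pattern excluded)
// X:      P x J binary pattern matrix
// Returns kept draws of N, p0 and alpha.
// [[Rcpp::export(name = ".lcmcr_gibbs_cpp")]]
List lcmcr_gibbs_cpp(IntegerVector counts, IntegerMatrix X, int K,
                     double a_alpha, double b_alpha,
                     int n_samples, int burn_in, int thinning,
                     double lambda_a, double lambda_b) {
  const int P = X.nrow();
  const int J = X.ncol();
  const double eps = 1e-12;
  int n_obs = 0;
  for (int p = 0; p < P; ++p) n_obs += counts[p];

  std::vector<double> lam(J * K);      // lam[j + J*k]
  for (size_t i = 0; i < lam.size(); ++i) lam[i] = R::runif(0.2, 0.8);
  std::vector<double> V(K, 0.5);
  V[K - 1] = 1.0;
  double alpha = a_alpha / b_alpha;

  std::vector<double> pi_k(K), L0(K), w(K), m(K), tail(K + 1);
  std::vector<double> Lobs(P * K);     // Lobs[p + P*k]
  std::vector<double> capt(J * K), mz(K);
  std::vector<int> zcnt(K);

  NumericVector draws_N(n_samples), draws_p0(n_samples), draws_alpha(n_samples);
  const int n_iter = burn_in + n_samples * thinning;
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // stick weights
    double rem = 1.0;
    for (int k = 0; k < K; ++k) {
      pi_k[k] = V[k] * rem;
      rem *= (1.0 - V[k]);
    }
    // pattern likelihoods per class and zero-history probability
    double p0 = 0.0;
    for (int k = 0; k < K; ++k) {
      double l0 = 1.0;
      for (int j = 0; j < J; ++j) l0 *= (1.0 - lam[j + J * k]);
      L0[k] = l0;
      p0 += pi_k[k] * l0;
    }
    if (p0 < eps) p0 = eps;
    if (p0 > 1.0 - eps) p0 = 1.0 - eps;
    double n0d = R::rnbinom(static_cast<double>(n_obs), 1.0 - p0);
    if (!R_FINITE(n0d) || n0d > 2147483646.0)
      stop("non-finite zero-history draw at iteration %d (p0 = %g)", it, p0);
    int n0 = static_cast<int>(n0d);

    // class allocation: zero-history block, then each observed pattern
    std::fill(m.begin(), m.end(), 0.0);
    std::fill(capt.begin(), capt.end(), 0.0);
    if (n0 > 0) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { w[k] = pi_k[k] * L0[k]; tot += w[k]; }
      for (int k = 0; k < K; ++k) w[k] /= tot;
      rmultinom(n0, w.data(), K, zcnt.data());
      for (int k = 0; k < K; ++k) m[k] += zcnt[k];
    }
    for (int p = 0; p < P; ++p) {
      if (counts[p] == 0) continue;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double l = 1.0;
        for (int j = 0; j < J; ++j) {
          const double lj = lam[j + J * k];
          l *= X(p, j) ? lj : (1.0 - lj);
        }
        w[k] = pi_k[k] * l;
        tot += w[k];
      }
      for (int k = 0; k < K; ++k) w[k] /= tot;
      rmultinom(counts[p], w.data(), K, zcnt.data());
      for (int k = 0; k < K; ++k) {
        if (zcnt[k] == 0) continue;
        m[k] += zcnt[k];
        for (int j = 0; j < J; ++j)
          if (X(p, j)) capt[j + J * k] += zcnt[k];
      }
    }

    // capture probabilities
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J; ++j) {
        double c = capt[j + J * k];
        double l = R::rbeta(lambda_a + c, lambda_b + m[k] - c);
        if (l < eps) l = eps;
        if (l > 1.0 - eps) l = 1.0 - eps;
        lam[j + J * k] = l;
      }

    // sticks and concentration
    if (K > 1) {
      tail[K] = 0.0;
      for (int k = K - 1; k >= 0; --k) tail[k] = tail[k + 1] + m[k];
      double slog = 0.0;
      for (int k = 0; k < K - 1; ++k) {
        double v = R::rbeta(1.0 + m[k], alpha + tail[k + 1]);
        if (v < eps) v = eps;
        if (v > 1.0 - eps) v = 1.0 - eps;
        V[k] = v;
        slog += std::log1p(-v);
      }
      alpha = R::rgamma(a_alpha + K - 1, 1.0 / (b_alpha - slog));
      if (!R_FINITE(alpha))
        stop("non-finite sampler state at iteration %d", it);
    }

    if (kept < n_samples && it > burn_in &&
        (it - burn_in) % thinning == 0) {
      draws_N[kept] = n_obs + static_cast<double>(n0);
      draws_p0[kept] = p0;
      draws_alpha[kept] = alpha;
      ++kept;
    }
  }

  return List::create(_["N"] = draws_N, _["p0"] = draws_p0,
                      _["alpha"] = draws_alpha);
}
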