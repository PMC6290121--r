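#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the {0,1} Ising model
//   P(x) ∝ exp(sum_j tau_j x_j + sum_{j<k} omega_jk x_j x_k),
// using the full conditional P(x_j = 1 | x_-j) = logistic(tau_j + sum_k omega_jk x_k).
// Systematic sweeps; draws from R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
IntegerMatrix gibbs_ising(const NumericVector& tau, const NumericMatrix& omega,
                          int n, int burnin, int thin) {
  const int p = tau.size();
  IntegerMatrix out(n, p);
  std::vector<int> x(p, 0);

  // random initial state
  for (int j = 0; j < p; ++j) x[j] = (unif_rand() < 0.5) ? 1 : 0;

  auto sweep = [&]() {
    for (int j = 0; j < p; ++j) {
      double h = tau[j];
      for (int k = 0; k < p; ++k)
        if (x[k]) h += omega(j, k);
      const double pr = 1.0 / (1.0 + std::exp(-h));
      x[j] = (unif_rand() < pr) ? 1 : 0;
    }
  };

  for (int s = 0; s < burnin; ++s) sweep();
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < thin; ++s) sweep();
    for (int j = 0; j < p; ++j) out(i, j) = x[j];
  }
  return out;
}
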