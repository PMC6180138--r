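#include <Rcpp.h>
using namespace Rcpp;

// Sequential-scan Gibbs sampler for a {0,1} Ising model with conditionals
// P(x_i = 1 | x_-i) = logistic(tau_i + sum_j W_ij x_j).
// Uses R's RNG stream, so set.seed() on the R side makes draws reproducible.

// [[Rcpp::export(name = ".gibbs_sample_cpp")]]
IntegerMatrix gibbs_sample_cpp(const NumericVector& tau, const NumericMatrix& W,
                               int n_samples, int burn_in, int thin) {
  const int p = tau.size();
  IntegerMatrix out(n_samples, p);
  std::vector<int> x(p);
  RNGScope scope;
  for (int i = 0; i < p; ++i) x[i] = (unif_rand() < 0.5) ? 1 : 0;

  const int total = burn_in + n_samples * thin;
  int kept = 0;
  for (int s = 0; s < total; ++s) {
    for (int i = 0; i < p; ++i) {
      double eta = tau[i];
      for (int j = 0; j < p; ++j)
        if (x[j]) eta += W(i, j);
      double pr = 1.0 / (1.0 + std::exp(-eta));
      x[i] = (unif_rand() < pr) ? 1 : 0;
    }
    if (s >= burn_in && (s - burn_in) % thin == thin - 1) {
      for (int i = 0; i < p; ++i) out(kept, i) = x[i];
      ++kept;
      if (kept == n_samples) break;
    }
  }
  return out;
}
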