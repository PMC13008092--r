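#include <Rcpp.h>
using namespace Rcpp;

// Single-chain Gibbs sampler for a pairwise binary Markov random field
// P(x) propto exp(sum_i tau_i x_i + sum_{i<j} Omega_ij x_i x_j), x in {0,1}^p.
//
// thresholds is an n x p matrix: row r holds the effective (covariate-shifted)
// thresholds for the respondent whose draw is recorded r-th. The chain runs
// burn_in full sweeps under row 0's thresholds, then for each respondent r
// advances `thinning` sweeps under row r's thresholds and records the state.
// Uses R's RNG so set.seed() gives reproducibility.
// [[Rcpp::export(name = ".gibbs_sample")]]
IntegerMatrix gibbs_sample(NumericMatrix thresholds, NumericMatrix couplings,
                           int burn_in, int thinning) {
  const int n = thresholds.nrow();
  const int p = thresholds.ncol();
  IntegerMatrix out(n, p);
  std::vector<int> x(p);
  for (int i = 0; i < p; ++i) x[i] = (unif_rand() < 0.5) ? 1 : 0;

  auto sweep = [&](int row) {
    for (int i = 0; i < p; ++i) {
      double eta = thresholds(row, i);
      for (int j = 0; j < p; ++j)
        if (x[j]) eta += couplings(i, j);
      // couplings has zero diagonal so x[i] never feeds its own update
      double pr = 1.0 / (1.0 + std::exp(-eta));
      x[i] = (unif_rand() < pr) ? 1 : 0;
    }
  };

  for (int s = 0; s < burn_in; ++s) sweep(0);
  for (int r = 0; r < n; ++r) {
    for (int s = 0; s < thinning; ++s) sweep(r);
    for (int i = 0; i < p; ++i) out(r, i) = x[i];
  }
  return out;
}
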