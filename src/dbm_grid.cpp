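#include <Rcpp.h>
using namespace Rcpp;

// Trial-wise predictive P(stop) sequences for a batch of DBM parameter
// triples sharing one outcome history. Each column of the result is the
// P(stop) sequence of one (alpha, m, s) candidate; the per-candidate filter
// is the same leaky beta-Bernoulli recursion as the R-level dbm_pstop(),
// evaluated on bin midpoints of (0, 1). Normalization is carried as a
// scalar mass sum folded into the leak coefficient, which is algebraically
// identical to renormalizing after every multiply and keeps 288-trial
// blocks far from underflow.
// [[Rcpp::export]]
NumericMatrix dbm_pstop_grid_cpp(IntegerVector outcomes,
                                 NumericVector alpha,
                                 NumericVector m,
                                 NumericVector s,
                                 int n_grid) {
  const int n_trials = outcomes.size();
  const int n_cand = alpha.size();
  if (m.size() != n_cand || s.size() != n_cand)
    stop("alpha, m and s must have equal length");
  if (n_grid < 50) stop("n_grid must be at least 50");

  std::vector<double> grid(n_grid), one_minus(n_grid);
  for (int i = 0; i < n_grid; ++i) {
    grid[i] = (i + 0.5) / n_grid;
    one_minus[i] = 1.0 - grid[i];
  }

  NumericMatrix out(n_trials, n_cand);
  std::vector<double> prior(n_grid), w(n_grid);

  for (int j = 0; j < n_cand; ++j) {
    const double a_sh = m[j] * s[j];
    const double b_sh = (1.0 - m[j]) * s[j];
    const double al = alpha[j];
    double z = 0.0;
    for (int i = 0; i < n_grid; ++i) {
      prior[i] = R::dbeta(grid[i], a_sh, b_sh, 0);
      z += prior[i];
    }
    for (int i = 0; i < n_grid; ++i) {
      prior[i] /= z;
      w[i] = prior[i];
    }
    z = 1.0;  // w is normalized
    for (int k = 0; k < n_trials; ++k) {
      // leak toward the prior (k = 0: the prior itself), predict, update
      const double c1 = (k > 0) ? al / z : 1.0 / z;
      const double c2 = (k > 0) ? 1.0 - al : 0.0;
      const double* lik = (outcomes[k] == 1) ? grid.data()
                                             : one_minus.data();
      double pred = 0.0, znew = 0.0;
      for (int i = 0; i < n_grid; ++i) {
        double wi = c1 * w[i] + c2 * prior[i];
        pred += grid[i] * wi;
        wi *= lik[i];
        znew += wi;
        w[i] = wi;
      }
      out(k, j) = pred;
      z = znew;
    }
  }
  return out;
}
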