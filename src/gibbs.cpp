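#include "common.h"
using namespace Rcpp;

// Collapsed Gibbs sampling of fragment assignments.  theta is integrated
// out under a symmetric Dirichlet(alpha) prior over the M+1 components
// (0 = noise); each read's assignment is resampled conditional on all
// other assignments:
//   P(z_n = a | z_-n) propto (alpha + c_-n[t(a)]) * w_a
// with the noise outcome handled analogously through noise_w.  One count
// vector is recorded per sweep after burn-in (thinning configurable).
// Uses R's RNG so runs are reproducible under set.seed().

// [[Rcpp::export]]
List cpp_gibbs(IntegerVector offsets, IntegerVector tid, NumericVector w,
               NumericVector noise_w, int M, double alpha,
               NumericVector theta_ml, int n_burn, int n_keep, int thin) {
  int n = (int) offsets.size() - 1;
  std::vector<long long> c(M + 1, 0);
  // initial mapping of each fragment sampled from the ML responsibilities
  std::vector<int> z(n, 0);
  for (int r = 0; r < n; ++r) {
    double denom = theta_ml[0] * noise_w[r];
    for (int a = offsets[r]; a < offsets[r + 1]; ++a)
      denom += theta_ml[tid[a]] * w[a];
    if (denom <= 0.0)
      stop("read %d has zero likelihood under the ML parameters", r + 1);
    double u = unif_rand() * denom;
    double acc = theta_ml[0] * noise_w[r];
    int pick = 0;
    for (int a = offsets[r]; a < offsets[r + 1] && u > acc; ++a) {
      acc += theta_ml[tid[a]] * w[a];
      pick = a + 1;
    }
    z[r] = pick;
  }
  for (int r = 0; r < n; ++r)
    c[z[r] == 0 ? 0 : tid[z[r] - 1]] += 1;

  IntegerMatrix out(n_keep, M + 1);
  std::vector<double> prob;
  int kept = 0;
  long long sweep = 0;
  while (kept < n_keep) {
    ++sweep;
    for (int r = 0; r < n; ++r) {
      int cur = z[r] == 0 ? 0 : tid[z[r] - 1];
      c[cur] -= 1;
      int ncand = offsets[r + 1] - offsets[r];
      prob.resize(ncand + 1);
      double tot = (alpha + (double) c[0]) * noise_w[r];
      prob[0] = tot;
      for (int k = 0; k < ncand; ++k) {
        int a = offsets[r] + k;
        tot += (alpha + (double) c[tid[a]]) * w[a];
        prob[k + 1] = tot;
      }
      if (tot <= 0.0)
        stop("read %d has zero conditional mass in the Gibbs sweep", r + 1);
      double u = unif_rand() * tot;
      int pick = 0;
      while (pick <= ncand && u > prob[pick]) ++pick;
      if (pick > ncand) pick = ncand;
      if (pick == 0) {
        z[r] = 0;
        c[0] += 1;
      } else {
        z[r] = offsets[r] + pick;       // 1-based candidate index
        c[tid[offsets[r] + pick - 1]] += 1;
      }
    }
    if (sweep > n_burn && ((sweep - n_burn - 1) % thin == 0)) {
      for (int i = 0; i <= M; ++i) out(kept, i) = (int) c[i];
      ++kept;
    }
  }
  return List::create(_["counts"] = out, _["assign"] = wrap(z),
                      _["sweeps"] = (double) sweep);
}
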