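#include "common.h"
using namespace Rcpp;

// Expectation-maximization over the candidate-alignment structure.
// Candidates are stored CSR-style: read r owns candidates
// offsets[r] .. offsets[r+1]-1 (0-based into tid/w).  tid is 1..M; the
// noise component is index 0.  w excludes the theta factor.  The M-step
// sets theta_i proportional to c_i / m_i (i >= 1) and theta_0 to c_0,
// which is the repeat/poly(A) filter bias correction (m_i = probability
// that a fragment from transcript i survives the read filters).

static double e_pass(const IntegerVector &off, const IntegerVector &tid,
                     const NumericVector &w, const NumericVector &noise_w,
                     const std::vector<double> &theta,
                     std::vector<double> &counts) {
  int n = (int) off.size() - 1;
  std::fill(counts.begin(), counts.end(), 0.0);
  double ll = 0.0;
  for (int r = 0; r < n; ++r) {
    double denom = theta[0] * noise_w[r];
    for (int a = off[r]; a < off[r + 1]; ++a)
      denom += theta[tid[a]] * w[a];
    if (denom <= 0.0)
      stop("read %d has zero total likelihood (no noise mass and no usable alignment)",
           r + 1);
    counts[0] += theta[0] * noise_w[r] / denom;
    for (int a = off[r]; a < off[r + 1]; ++a)
      counts[tid[a]] += theta[tid[a]] * w[a] / denom;
    ll += std::log(denom);
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_em(IntegerVector offsets, IntegerVector tid, NumericVector w,
            NumericVector noise_w, NumericVector theta0, NumericVector m,
            int max_iters, double rel_tol, double theta_min) {
  int M = (int) m.size();
  int n = (int) offsets.size() - 1;
  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> counts(M + 1), tnew(M + 1);
  double ll = R_NegInf;
  int it = 0;
  bool converged = false;
  for (it = 0; it < max_iters; ++it) {
    ll = e_pass(offsets, tid, w, noise_w, theta, counts);
    tnew[0] = counts[0];
    for (int i = 1; i <= M; ++i) tnew[i] = counts[i] / m[i - 1];
    double tot = 0.0;
    for (int i = 0; i <= M; ++i) tot += tnew[i];
    for (int i = 0; i <= M; ++i) tnew[i] /= tot;
    bool ok = true;
    for (int i = 0; i <= M; ++i) {
      if (theta[i] >= theta_min &&
          std::fabs(tnew[i] - theta[i]) / theta[i] >= rel_tol) {
        ok = false;
        break;
      }
    }
    theta = tnew;
    if (ok) { converged = true; ++it; break; }
  }
  // expected counts and log-likelihood at the final theta
  ll = e_pass(offsets, tid, w, noise_w, theta, counts);
  (void) n;
  return List::create(_["theta"] = wrap(theta), _["counts"] = wrap(counts),
                      _["iters"] = it, _["loglik"] = ll,
                      _["converged"] = converged);
}

// [[Rcpp::export]]
List cpp_e_counts(IntegerVector offsets, IntegerVector tid, NumericVector w,
                  NumericVector noise_w, NumericVector theta, int M) {
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> counts(M + 1);
  double ll = e_pass(offsets, tid, w, noise_w, th, counts);
  return List::create(_["counts"] = wrap(counts), _["loglik"] = ll);
}

// Per-candidate posterior probabilities (and per-read noise posterior).
// [[Rcpp::export]]
List cpp_responsibilities(IntegerVector offsets, IntegerVector tid,
                          NumericVector w, NumericVector noise_w,
                          NumericVector theta) {
  int n = (int) offsets.size() - 1;
  NumericVector post(w.size()), noise_post(n);
  double ll = 0.0;
  for (int r = 0; r < n; ++r) {
    double denom = theta[0] * noise_w[r];
    for (int a = offsets[r]; a < offsets[r + 1]; ++a)
      denom += theta[tid[a]] * w[a];
    if (denom <= 0.0)
      stop("read %d has zero total likelihood (no noise mass and no usable alignment)",
           r + 1);
    noise_post[r] = theta[0] * noise_w[r] / denom;
    for (int a = offsets[r]; a < offsets[r + 1]; ++a)
      post[a] = theta[tid[a]] * w[a] / denom;
    ll += std::log(denom);
  }
  return List::create(_["post"] = post, _["noise_post"] = noise_post,
                      _["loglik"] = ll);
}
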