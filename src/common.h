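#ifndef RNAQUANT_COMMON_H
#define RNAQUANT_COMMON_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default:  return 4;  // N / ambiguous
  }
}

inline char comp_char(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default:  return 'N';
  }
}

inline std::string revcomp(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_char(s[i]);
  return out;
}

// Probability that a fragment start falls at position p of n possible
// positions, under a binned read start position distribution (RSPD).
// Bin weights are split evenly among the positions mapping to the bin and
// the result is renormalized so the n positions sum to one.  A single-bin
// RSPD is the uniform distribution.
inline double rspd_prob(int p, int n, const std::vector<double> &w) {
  const int B = (int) w.size();
  if (B == 1 || n <= 0) return 1.0 / n;
  const long long nB = (long long) n;
  int bin = (int) (((long long) p * B) / nB);
  long long hi = ((long long)(bin + 1) * nB + B - 1) / B;
  long long lo = ((long long) bin * nB + B - 1) / B;
  int nb = (int) (hi - lo);
  double z = 1.0;
  if (n < B) {              // some bins unoccupied: renormalize explicitly
    z = 0.0;
    int prev = -1;
    for (int q = 0; q < n; ++q) {
      int b = (int) (((long long) q * B) / nB);
      if (b != prev) { z += w[b]; prev = b; }
    }
  }
  return (w[bin] / nb) / z;
}

#endif
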