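#include "common.h"
using namespace Rcpp;

// Truncated-renormalized pmf helpers.  A length distribution is passed as
// (min_len, pmf over min_len..max_len).  cum[k] is the cumulative mass up
// to min_len + k.

static double trunc_denom(const std::vector<double> &cum, int min_len,
                          int limit) {
  if (limit < min_len) return 0.0;
  int k = limit - min_len;
  if (k >= (int) cum.size()) k = (int) cum.size() - 1;
  return cum[k];
}

static std::vector<double> cumsum(const NumericVector &p) {
  std::vector<double> c(p.size());
  double s = 0;
  for (R_xlen_t i = 0; i < p.size(); ++i) { s += p[i]; c[i] = s; }
  return c;
}

// Position factors for single-end alignments: the fragment length is
// latent and is marginalized over all feasible values,
//   w(s, o) = P(o) * sum_f lambdaF(f | l) * rspd(s_f | l - f + 1) * lambdaR(L | f)
// where for a forward alignment the fragment starts at the read start and
// for a reverse alignment the fragment ends at the read end.
// [[Rcpp::export]]
NumericVector cpp_se_pos_factors(IntegerVector tlen, IntegerVector pos,
                                 IntegerVector orient, IntegerVector rlen,
                                 int frag_min, NumericVector frag_pmf,
                                 int read_min, NumericVector read_pmf,
                                 NumericVector rspd, bool strand_specific) {
  std::vector<double> fcum = cumsum(frag_pmf);
  std::vector<double> rcum = cumsum(read_pmf);
  int frag_max = frag_min + (int) frag_pmf.size() - 1;
  int read_max = read_min + (int) read_pmf.size() - 1;
  std::vector<double> w(rspd.begin(), rspd.end());
  R_xlen_t n = tlen.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int l = tlen[i], p = pos[i], L = rlen[i], o = orient[i];
    double Po = strand_specific ? (o == 0 ? 1.0 : 0.0) : 0.5;
    if (Po == 0.0) { out[i] = 0.0; continue; }
    double fden = trunc_denom(fcum, frag_min, l);
    if (fden <= 0.0 || L < read_min || L > read_max) { out[i] = 0.0; continue; }
    double acc = 0.0;
    int flo = std::max(frag_min, L);
    int fhi = std::min(frag_max, l);
    for (int f = flo; f <= fhi; ++f) {
      int s = (o == 0) ? p : p + L - f;      // fragment start for this f
      if (s < 0 || s + f > l) continue;
      double lf = frag_pmf[f - frag_min] / fden;
      if (lf <= 0.0) continue;
      double rden = trunc_denom(rcum, read_min, f);
      if (rden <= 0.0) continue;
      double lr = read_pmf[L - read_min] / rden;
      acc += lf * rspd_prob(s, l - f + 1, w) * lr;
    }
    out[i] = Po * acc;
  }
  return out;
}

// Position factors for paired-end alignments (fragment length observed):
//   w = P(o) * lambdaF(f | l) * rspd(s | l - f + 1)
//         * lambdaR(L1 | f) * lambdaR(L2 | f)
// [[Rcpp::export]]
NumericVector cpp_pe_pos_factors(IntegerVector tlen, IntegerVector pos,
                                 IntegerVector flen, IntegerVector orient,
                                 IntegerVector rlen1, IntegerVector rlen2,
                                 int frag_min, NumericVector frag_pmf,
                                 int read_min, NumericVector read_pmf,
                                 NumericVector rspd, bool strand_specific) {
  std::vector<double> fcum = cumsum(frag_pmf);
  std::vector<double> rcum = cumsum(read_pmf);
  int frag_max = frag_min + (int) frag_pmf.size() - 1;
  int read_max = read_min + (int) read_pmf.size() - 1;
  std::vector<double> w(rspd.begin(), rspd.end());
  R_xlen_t n = tlen.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int l = tlen[i], s = pos[i], f = flen[i], o = orient[i];
    int L1 = rlen1[i], L2 = rlen2[i];
    double Po = strand_specific ? (o == 0 ? 1.0 : 0.0) : 0.5;
    double res = 0.0;
    if (Po > 0.0 && f >= frag_min && f <= frag_max && s >= 0 && s + f <= l &&
        L1 >= read_min && L1 <= read_max && L2 >= read_min && L2 <= read_max &&
        L1 <= f && L2 <= f) {
      double fden = trunc_denom(fcum, frag_min, l);
      double rden = trunc_denom(rcum, read_min, f);
      if (fden > 0.0 && rden > 0.0) {
        double lf = frag_pmf[f - frag_min] / fden;
        double lr1 = read_pmf[L1 - read_min] / rden;
        double lr2 = read_pmf[L2 - read_min] / rden;
        res = Po * lf * rspd_prob(s, l - f + 1, w) * lr1 * lr2;
      }
    }
    out[i] = res;
  }
  return out;
}

// RSPD position probabilities for all n start positions (R-facing helper).
// [[Rcpp::export]]
NumericVector cpp_rspd_positions(NumericVector rspd, int n) {
  std::vector<double> w(rspd.begin(), rspd.end());
  NumericVector out(n);
  for (int p = 0; p < n; ++p) out[p] = rspd_prob(p, n, w);
  return out;
}

// Mismatch extraction: for each candidate alignment, the read positions at
// which the read character differs from the (orientation-corrected)
// reference character.  Reverse alignments compare the read against the
// reverse complement of the transcript window, so mismatch positions are
// in read coordinates (matching the quality string).
// [[Rcpp::export]]
List cpp_mismatches(CharacterVector reads, IntegerVector cand_read,
                    IntegerVector cand_tid, IntegerVector cand_pos,
                    IntegerVector cand_orient, CharacterVector tseqs) {
  std::vector<std::string> rs(reads.size()), ts(tseqs.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) rs[i] = as<std::string>(reads[i]);
  for (R_xlen_t i = 0; i < tseqs.size(); ++i) ts[i] = as<std::string>(tseqs[i]);
  std::vector<int> o_cand, o_pos, o_rc, o_cc;
  for (R_xlen_t a = 0; a < cand_read.size(); ++a) {
    const std::string &rd = rs[cand_read[a] - 1];
    const std::string &s = ts[cand_tid[a] - 1];
    int L = (int) rd.size(), p = cand_pos[a];
    for (int i = 0; i < L; ++i) {
      char rc = rd[i];
      char cc = (cand_orient[a] == 0) ? s[p + i] : comp_char(s[p + L - 1 - i]);
      int r = base_code(rc), c = base_code(cc);
      if (r != c || r > 3) {
        o_cand.push_back((int) a + 1);
        o_pos.push_back(i);
        o_rc.push_back(r);
        o_cc.push_back(c);
      }
    }
  }
  return List::create(_["cand"] = wrap(o_cand), _["pos"] = wrap(o_pos),
                      _["read_char"] = wrap(o_rc), _["ref_char"] = wrap(o_cc));
}

// [[Rcpp::export]]
List cpp_encode_seqs(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  IntegerVector off(n + 1);
  std::vector<int> codes;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    off[i + 1] = off[i] + (int) s.size();
    for (size_t j = 0; j < s.size(); ++j) codes.push_back(base_code(s[j]));
  }
  return List::create(_["offsets"] = off, _["codes"] = wrap(codes));
}

// [[Rcpp::export]]
List cpp_encode_quals(CharacterVector quals, int phred_offset) {
  R_xlen_t n = quals.size();
  IntegerVector off(n + 1);
  std::vector<int> codes;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(quals[i]);
    off[i + 1] = off[i] + (int) s.size();
    for (size_t j = 0; j < s.size(); ++j)
      codes.push_back((int) s[j] - phred_offset);
  }
  return List::create(_["offsets"] = off, _["codes"] = wrap(codes));
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}
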