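#include "common.h"
using namespace Rcpp;

// Seed-and-count all-hits aligner.  A read aligns to (transcript, pos,
// orientation) when its first seed_len bases (of the read for the forward
// orientation, of its reverse complement for the reverse orientation) match
// the transcript window starting at pos with at most max_mm mismatches, and
// the full read fits within the transcript.  Mirrors a Bowtie-style
// "-n" seed policy.  The indexed path enumerates all Hamming-neighbour
// seeds of the read and looks them up in an exact k-mer index, which is
// equivalent to the exhaustive scan for N-free sequences.

typedef std::unordered_map<uint64_t, std::vector<uint64_t> > SeedIndex;

static bool encode_kmer(const char *s, int k, uint64_t &key) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c > 3) return false;
    v = (v << 2) | (uint64_t) c;
  }
  key = v;
  return true;
}

static void build_index(const std::vector<std::string> &tseq, int seed_len,
                        SeedIndex &idx) {
  for (size_t t = 0; t < tseq.size(); ++t) {
    const std::string &s = tseq[t];
    if ((int) s.size() < seed_len) continue;
    for (size_t p = 0; p + seed_len <= s.size(); ++p) {
      uint64_t key;
      if (!encode_kmer(s.c_str() + p, seed_len, key))
        continue;                       // windows containing N are unseedable
      idx[key].push_back(((uint64_t) t << 32) | (uint64_t) p);
    }
  }
}

struct Hit { int tid; int pos; int orient; };

// Enumerate seeds within Hamming distance max_mm of `seed` and collect the
// index hits for which the full read (read_len) fits in the transcript.
// Returns false if the number of hits reached `cap` (collection aborted).
static bool collect_hits(const SeedIndex &idx, uint64_t seed, int seed_len,
                         int max_mm, int orient, int read_len,
                         const std::vector<int> &tlen,
                         std::vector<Hit> &hits, size_t cap) {
  std::vector<uint64_t> keys;
  keys.push_back(seed);
  if (max_mm >= 1) {
    for (int i = 0; i < seed_len; ++i) {
      int sh = 2 * (seed_len - 1 - i);
      uint64_t cur = (seed >> sh) & 3ULL;
      for (uint64_t b = 0; b < 4; ++b) {
        if (b == cur) continue;
        keys.push_back((seed & ~(3ULL << sh)) | (b << sh));
      }
    }
  }
  if (max_mm >= 2) {
    for (int i = 0; i < seed_len; ++i) {
      int shi = 2 * (seed_len - 1 - i);
      uint64_t ci = (seed >> shi) & 3ULL;
      for (int j = i + 1; j < seed_len; ++j) {
        int shj = 2 * (seed_len - 1 - j);
        uint64_t cj = (seed >> shj) & 3ULL;
        for (uint64_t bi = 0; bi < 4; ++bi) {
          if (bi == ci) continue;
          uint64_t k1 = (seed & ~(3ULL << shi)) | (bi << shi);
          for (uint64_t bj = 0; bj < 4; ++bj) {
            if (bj == cj) continue;
            keys.push_back((k1 & ~(3ULL << shj)) | (bj << shj));
          }
        }
      }
    }
  }
  if (max_mm >= 3)
    stop("seed mismatch budgets above 2 are not supported by the indexed aligner");
  for (size_t k = 0; k < keys.size(); ++k) {
    SeedIndex::const_iterator it = idx.find(keys[k]);
    if (it == idx.end()) continue;
    const std::vector<uint64_t> &v = it->second;
    for (size_t h = 0; h < v.size(); ++h) {
      int t = (int) (v[h] >> 32);
      int p = (int) (v[h] & 0xffffffffULL);
      if (p + read_len > tlen[t]) continue;
      Hit hit; hit.tid = t; hit.pos = p; hit.orient = orient;
      hits.push_back(hit);
      if (hits.size() >= cap) return false;
    }
  }
  return true;
}

static std::vector<std::string> as_strings(const CharacterVector &x) {
  std::vector<std::string> out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = as<std::string>(x[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_align_reads(CharacterVector reads, CharacterVector tseqs,
                     int seed_len, int max_mm, int max_hits,
                     bool forward_only) {
  if (seed_len < 1 || seed_len > 32)
    stop("indexed aligner requires 1 <= seed_len <= 32");
  std::vector<std::string> ts = as_strings(tseqs);
  std::vector<int> tlen(ts.size());
  for (size_t i = 0; i < ts.size(); ++i) tlen[i] = (int) ts[i].size();
  SeedIndex idx;
  build_index(ts, seed_len, idx);

  std::vector<int> o_read, o_tid, o_pos, o_or;
  IntegerVector nhits(reads.size());
  LogicalVector capped(reads.size());
  size_t cap = (size_t) max_hits;

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    int L = (int) rd.size();
    std::vector<Hit> hits;
    bool ok = true;
    uint64_t seed;
    if (L >= seed_len && encode_kmer(rd.c_str(), seed_len, seed))
      ok = collect_hits(idx, seed, seed_len, max_mm, 0, L, tlen, hits, cap);
    if (ok && !forward_only) {
      std::string rc = revcomp(rd);
      if (L >= seed_len && encode_kmer(rc.c_str(), seed_len, seed))
        ok = collect_hits(idx, seed, seed_len, max_mm, 1, L, tlen, hits, cap);
    }
    if (!ok) {                      // hit the cap: treat as "many alignments"
      capped[r] = true;
      nhits[r] = max_hits;
      continue;
    }
    std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
      if (a.tid != b.tid) return a.tid < b.tid;
      if (a.pos != b.pos) return a.pos < b.pos;
      return a.orient < b.orient;
    });
    nhits[r] = (int) hits.size();
    for (size_t h = 0; h < hits.size(); ++h) {
      o_read.push_back((int) r + 1);
      o_tid.push_back(hits[h].tid + 1);
      o_pos.push_back(hits[h].pos);
      o_or.push_back(hits[h].orient);
    }
  }
  return List::create(_["read"] = wrap(o_read), _["tid"] = wrap(o_tid),
                      _["pos"] = wrap(o_pos), _["orient"] = wrap(o_or),
                      _["nhits"] = nhits, _["capped"] = capped);
}

// Exhaustive scan aligner: reference implementation of the same policy,
// deterministic order (transcript, then offset, then forward before
// reverse).  Handles N (never matches any base).
// [[Rcpp::export]]
List cpp_scan_align(std::string read, CharacterVector tseqs, int seed_len,
                    int max_mm, bool forward_only) {
  int L = (int) read.size();
  std::string rc = revcomp(read);
  std::vector<int> o_tid, o_pos, o_or;
  for (R_xlen_t t = 0; t < tseqs.size(); ++t) {
    std::string s = as<std::string>(tseqs[t]);
    int n = (int) s.size();
    for (int p = 0; p + L <= n; ++p) {
      for (int orient = 0; orient < (forward_only ? 1 : 2); ++orient) {
        const std::string &q = orient == 0 ? read : rc;
        int mm = 0;
        for (int i = 0; i < seed_len && mm <= max_mm; ++i) {
          int a = base_code(q[i]), b = base_code(s[p + i]);
          if (a > 3 || b > 3 || a != b) ++mm;
        }
        if (mm <= max_mm) {
          o_tid.push_back((int) t + 1);
          o_pos.push_back(p);
          o_or.push_back(orient);
        }
      }
    }
  }
  return List::create(_["tid"] = wrap(o_tid), _["pos"] = wrap(o_pos),
                      _["orient"] = wrap(o_or));
}

// Alignment counts (both orientations, capped) for a batch of query reads
// against a transcript set -- used for the repeat-pass probabilities m_i.
// [[Rcpp::export]]
IntegerVector cpp_hit_counts(CharacterVector queries, CharacterVector tseqs,
                             int seed_len, int max_mm, int cap,
                             bool forward_only) {
  if (seed_len < 1 || seed_len > 32)
    stop("indexed aligner requires 1 <= seed_len <= 32");
  std::vector<std::string> ts = as_strings(tseqs);
  std::vector<int> tlen(ts.size());
  for (size_t i = 0; i < ts.size(); ++i) tlen[i] = (int) ts[i].size();
  SeedIndex idx;
  build_index(ts, seed_len, idx);
  IntegerVector out(queries.size());
  for (R_xlen_t r = 0; r < queries.size(); ++r) {
    std::string rd = as<std::string>(queries[r]);
    int L = (int) rd.size();
    std::vector<Hit> hits;
    bool ok = true;
    uint64_t seed;
    if (L >= seed_len && encode_kmer(rd.c_str(), seed_len, seed))
      ok = collect_hits(idx, seed, seed_len, max_mm, 0, L, tlen, hits,
                        (size_t) cap);
    if (ok && !forward_only) {
      std::string rc = revcomp(rd);
      if (L >= seed_len && encode_kmer(rc.c_str(), seed_len, seed))
        ok = collect_hits(idx, seed, seed_len, max_mm, 1, L, tlen, hits,
                          (size_t) cap);
    }
    out[r] = ok ? (int) hits.size() : cap;
  }
  return out;
}

// Mappability counts: for every read_len window of every transcript, does
// the window align (full length, <= max_mm mismatches, either strand) only
// to transcripts of its own gene?  Returns per-transcript totals.
// [[Rcpp::export]]
List cpp_mappability(CharacterVector tseqs, IntegerVector gene,
                     int read_len, int max_mm) {
  std::vector<std::string> ts = as_strings(tseqs);
  int M = (int) ts.size();
  // string-keyed index of all read_len windows (handles read_len > 32)
  std::unordered_map<std::string, std::vector<int> > idx;  // window -> tids
  for (int t = 0; t < M; ++t) {
    const std::string &s = ts[t];
    for (size_t p = 0; p + read_len <= s.size(); ++p)
      idx[s.substr(p, read_len)].push_back(t);
  }
  IntegerVector n_windows(M), n_within(M);
  for (int t = 0; t < M; ++t) {
    const std::string &s = ts[t];
    int g = gene[t];
    for (size_t p = 0; p + read_len <= s.size(); ++p) {
      ++n_windows[t];
      std::string w = s.substr(p, read_len);
      bool cross = false;
      // enumerate Hamming neighbours of the window (both strands)
      for (int strand = 0; strand < 2 && !cross; ++strand) {
        std::string q = strand == 0 ? w : revcomp(w);
        std::vector<std::string> keys;
        keys.push_back(q);
        const char B[4] = {'A', 'C', 'G', 'T'};
        if (max_mm >= 1) {
          for (int i = 0; i < read_len; ++i)
            for (int b = 0; b < 4; ++b) {
              if (q[i] == B[b]) continue;
              std::string k = q; k[i] = B[b]; keys.push_back(k);
            }
        }
        if (max_mm >= 2) {
          for (int i = 0; i < read_len; ++i)
            for (int j = i + 1; j < read_len; ++j)
              for (int bi = 0; bi < 4; ++bi) {
                if (q[i] == B[bi]) continue;
                for (int bj = 0; bj < 4; ++bj) {
                  if (q[j] == B[bj]) continue;
                  std::string k = q; k[i] = B[bi]; k[j] = B[bj];
                  keys.push_back(k);
                }
              }
        }
        if (max_mm >= 3) stop("mappability supports at most 2 mismatches");
        for (size_t k = 0; k < keys.size() && !cross; ++k) {
          std::unordered_map<std::string, std::vector<int> >::const_iterator
            it = idx.find(keys[k]);
          if (it == idx.end()) continue;
          for (size_t h = 0; h < it->second.size(); ++h)
            if (gene[it->second[h]] != g) { cross = true; break; }
        }
      }
      if (!cross) ++n_within[t];
    }
  }
  return List::create(_["n_windows"] = n_windows, _["n_within"] = n_within);
}
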