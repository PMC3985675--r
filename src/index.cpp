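#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Base codes: A=0, C=1, G=2, T=3, N=4. Seed symbols: 0='0', 1='T', 2='1'.
// Position-dependent letter class under the cyclically extended pattern:
//   '1' : four distinct classes (base identity)
//   'T' : purines {A,G} -> 0, pyrimidines {C,T} -> 1 (transition pairs merge)
//   '0' : single class
// N (or running off the sequence) is a terminator that sorts first and
// ends any comparison.
static inline int tclass(int base, int sym) {
  if (base >= 4) return -1;
  if (sym == 2) return base;
  if (sym == 1) return (base == 0 || base == 2) ? 0 : 1;
  return 0;
}

struct SuffixCmp {
  const uint8_t* seq;
  int len;
  const int* pat;
  int span;
  int maxdepth;
  bool operator()(int a, int b) const {
    for (int d = 0; d < maxdepth; ++d) {
      int sym = pat[d % span];
      int ca = (a + d < len) ? tclass(seq[a + d], sym) : -1;
      int cb = (b + d < len) ? tclass(seq[b + d], sym) : -1;
      if (ca != cb) return ca < cb;
      if (ca == -1) break;  // both terminated: equal prefix
    }
    return a < b;  // stable: ties ordered by position
  }
};

// [[Rcpp::export]]
IntegerVector build_subset_sa_cpp(IntegerVector ref, IntegerVector pattern,
                                  int step, int maxdepth) {
  int len = ref.size();
  if (len == 0) stop("empty reference");
  std::vector<uint8_t> seq(len);
  for (int i = 0; i < len; ++i) seq[i] = (uint8_t)ref[i];
  std::vector<int> pat(pattern.begin(), pattern.end());
  std::vector<int> pos;
  for (int p = 0; p < len; p += step)
    if (tclass(seq[p], pat[0]) >= 0) pos.push_back(p);
  SuffixCmp cmp{seq.data(), len, pat.data(), (int)pat.size(), maxdepth};
  std::sort(pos.begin(), pos.end(), cmp);
  return IntegerVector(pos.begin(), pos.end());
}

// Narrow [lo,hi) to entries whose transformed class at `depth` equals qc.
// Entries are sorted; suffixes that terminate before `depth` (class -1)
// sort to the front of the interval.
static inline void narrow(const std::vector<int>& sa, const uint8_t* seq,
                          int len, const int* pat, int span, int depth,
                          int qc, int& lo, int& hi) {
  int sym = pat[depth % span];
  // lower bound: first entry with class >= qc
  int l = lo, h = hi;
  while (l < h) {
    int mid = (l + h) / 2;
    int p = sa[mid];
    int c = (p + depth < len) ? tclass(seq[p + depth], sym) : -1;
    if (c < qc) l = mid + 1; else h = mid;
  }
  int nl = l;
  // upper bound: first entry with class > qc
  h = hi;
  while (l < h) {
    int mid = (l + h) / 2;
    int p = sa[mid];
    int c = (p + depth < len) ? tclass(seq[p + depth], sym) : -1;
    if (c <= qc) l = mid + 1; else h = mid;
  }
  lo = nl;
  hi = l;
}

// Adaptive seeds: from each query start q (q mod k == 0), the shortest
// pattern-prefix match occurring at most m times among indexed positions;
// emits every occurrence at that minimal length, or nothing if the classes
// diverge / an N is hit / the count never drops to <= m.
// Returns a 3-column matrix: query_pos, ref_pos, length (all 0-based).
// [[Rcpp::export]]
IntegerMatrix adaptive_seeds_cpp(IntegerVector query, IntegerVector ref,
                                 IntegerVector sa_in, IntegerVector pattern,
                                 int m, int k, int maxdepth) {
  int qlen = query.size(), rlen = ref.size();
  std::vector<uint8_t> qs(qlen), rs(rlen);
  for (int i = 0; i < qlen; ++i) qs[i] = (uint8_t)query[i];
  for (int i = 0; i < rlen; ++i) rs[i] = (uint8_t)ref[i];
  std::vector<int> sa(sa_in.begin(), sa_in.end());
  std::vector<int> pat(pattern.begin(), pattern.end());
  int span = (int)pat.size();
  std::vector<int> out;  // triples

  for (int q = 0; q < qlen; q += k) {
    int lo = 0, hi = (int)sa.size();
    for (int depth = 0; depth < maxdepth && q + depth < qlen; ++depth) {
      int qc = tclass(qs[q + depth], pat[depth % span]);
      if (qc < 0) break;  // N in query: no seed from this start
      narrow(sa, rs.data(), rlen, pat.data(), span, depth, qc, lo, hi);
      if (lo >= hi) break;  // no reference occurrence
      if (hi - lo <= m) {
        for (int i = lo; i < hi; ++i) {
          out.push_back(q);
          out.push_back(sa[i]);
          out.push_back(depth + 1);
        }
        break;
      }
    }
  }
  int nrec = (int)out.size() / 3;
  IntegerMatrix res(nrec, 3);
  for (int i = 0; i < nrec; ++i) {
    res(i, 0) = out[3 * i];
    res(i, 1) = out[3 * i + 1];
    res(i, 2) = out[3 * i + 2];
  }
  colnames(res) = CharacterVector::create("query_pos", "ref_pos", "length");
  return res;
}
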