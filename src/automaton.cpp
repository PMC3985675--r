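#include <Rcpp.h>
#include <map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Alignment letters are coded 0 = transversion, 1 = transition, 2 = match
// (same order as the -b/-f probability triples). Seed symbols are coded
// 0 = '0' (don't care), 1 = 'T' (transition-tolerant), 2 = '1' (match only).
// A symbol accepts a letter iff letter >= symbol under these codes.
static inline bool sym_accepts(int sym, int letter) { return letter >= sym; }

// DFA state: for each pattern, a bitmask of alive prefix lengths (bit j set
// <=> the last j letters match the pattern's length-j prefix, 1 <= j < span),
// plus the position phase mod c (new match attempts may only start at
// positions congruent to 0 mod c). The accepting state is absorbing.
typedef std::vector<uint64_t> MaskVec;

struct StateKey {
  MaskVec masks;
  int phase;
  bool operator<(const StateKey& o) const {
    if (phase != o.phase) return phase < o.phase;
    return masks < o.masks;
  }
};

// [[Rcpp::export]]
List build_seed_automaton_cpp(List patterns, int sparsity) {
  int np = patterns.size();
  std::vector<std::vector<int>> pats(np);
  for (int p = 0; p < np; ++p) {
    IntegerVector v = patterns[p];
    if (v.size() > 63) stop("pattern span > 63 not supported by the automaton");
    pats[p] = std::vector<int>(v.begin(), v.end());
  }
  const int ACCEPT = 0;  // reserved absorbing accept state
  std::map<StateKey, int> ids;
  std::vector<StateKey> keys;
  std::vector<std::array<int, 3>> trans;

  // accept state: self loops
  trans.push_back({ACCEPT, ACCEPT, ACCEPT});
  keys.push_back(StateKey());  // placeholder

  StateKey start;
  start.masks = MaskVec(np, 0);
  start.phase = 0;
  ids[start] = 1;
  keys.push_back(start);
  trans.push_back({-1, -1, -1});

  const size_t MAX_STATES = 1 << 19;
  for (size_t s = 1; s < keys.size(); ++s) {
    for (int letter = 0; letter < 3; ++letter) {
      const StateKey& cur = keys[s];
      StateKey nxt;
      nxt.masks = MaskVec(np, 0);
      nxt.phase = (cur.phase + 1) % sparsity;
      bool acc = false;
      for (int p = 0; p < np && !acc; ++p) {
        const std::vector<int>& pat = pats[p];
        int sp = (int)pat.size();
        uint64_t mm = cur.masks[p];
        for (int j = 0; j < sp; ++j) {
          bool alive = (j == 0) ? (cur.phase == 0) : ((mm >> j) & 1);
          if (alive && sym_accepts(pat[j], letter)) {
            if (j + 1 == sp) { acc = true; break; }
            nxt.masks[p] |= (uint64_t)1 << (j + 1);
          }
        }
      }
      int tid;
      if (acc) {
        tid = ACCEPT;
      } else {
        auto it = ids.find(nxt);
        if (it == ids.end()) {
          tid = (int)keys.size();
          if ((size_t)tid >= MAX_STATES)
            stop("seed automaton exceeded the state cap (%d states)", (int)MAX_STATES);
          ids[nxt] = tid;
          keys.push_back(nxt);
          trans.push_back({-1, -1, -1});
        } else {
          tid = it->second;
        }
      }
      trans[s][letter] = tid;
    }
  }

  int n = (int)trans.size();
  IntegerMatrix tm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) tm(i, a) = trans[i][a];
  return List::create(_["transitions"] = tm, _["start"] = 1,
                      _["accept"] = ACCEPT, _["n_states"] = n);
}

// Forward DP: probability mass per state after each letter; returns
// P(accepting state) after l letters.
// [[Rcpp::export]]
double automaton_sensitivity_cpp(IntegerMatrix transitions, int start,
                                 int accept, NumericVector probs, int l) {
  int n = transitions.nrow();
  std::vector<double> cur(n, 0.0), nxt(n);
  cur[start] = 1.0;
  for (int step = 0; step < l; ++step) {
    std::fill(nxt.begin(), nxt.end(), 0.0);
    for (int s = 0; s < n; ++s) {
      double m = cur[s];
      if (m == 0.0) continue;
      for (int a = 0; a < 3; ++a) nxt[transitions(s, a)] += m * probs[a];
    }
    cur.swap(nxt);
  }
  return cur[accept];
}

// One-shot build + DP (avoids shuttling the automaton through R in the
// hill-climbing inner loop).
// [[Rcpp::export]]
double sensitivity_dp_cpp(List patterns, int sparsity, NumericVector probs,
                          int l) {
  List aut = build_seed_automaton_cpp(patterns, sparsity);
  IntegerMatrix tm = aut["transitions"];
  return automaton_sensitivity_cpp(tm, aut["start"], aut["accept"], probs, l);
}

// Run the automaton on explicit letter strings (rows of a matrix);
// used for language-equivalence checks against the direct matcher.
// [[Rcpp::export]]
LogicalVector automaton_accepts_cpp(IntegerMatrix transitions, int start,
                                    int accept, IntegerMatrix strings) {
  int nr = strings.nrow(), nc = strings.ncol();
  LogicalVector out(nr);
  for (int i = 0; i < nr; ++i) {
    int s = start;
    for (int j = 0; j < nc; ++j) s = transitions(s, strings(i, j));
    out[i] = (s == accept);
  }
  return out;
}
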