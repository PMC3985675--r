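#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_set>
#include <climits>
using namespace Rcpp;

// Base codes A=0 C=1 G=2 T=3 N=4; submat is the 5x5 score table (N row/col
// already filled with the scheme's N score).

static const int NEG = INT_MIN / 4;

// ---------------------------------------------------------------------------
// Gapless X-drop extension, anchored at the seed's first column (q0, r0).
// Extends left then right along the diagonal; each direction stops when the
// running score drops more than y below its maximum; each flank is trimmed
// back to its maximum. The anchor is the column achieving the maximum
// running score over the trimmed segment (leftmost on ties).
struct GaplessRes { int off_l, off_r, score, anchor; };

static GaplessRes gapless_core(const int* q, int qn, const int* r,
                               int rn, int q0, int r0, const int* S, int y) {
  GaplessRes res;
  int base = S[q[q0] * 5 + r[r0]];
  int cum = 0, best = 0, bestoff = 0;
  for (int i = -1; q0 + i >= 0 && r0 + i >= 0; --i) {
    cum += S[q[q0 + i] * 5 + r[r0 + i]];
    if (cum > best) { best = cum; bestoff = i; }
    if (best - cum > y) break;
  }
  int gain_l = best, off_l = bestoff;
  cum = 0; best = 0; bestoff = 0;
  for (int i = 1; q0 + i < qn && r0 + i < rn; ++i) {
    cum += S[q[q0 + i] * 5 + r[r0 + i]];
    if (cum > best) { best = cum; bestoff = i; }
    if (best - cum > y) break;
  }
  res.off_l = off_l;
  res.off_r = bestoff;
  res.score = gain_l + base + best;
  int run = 0, amax = NEG, aoff = off_l;
  for (int i = off_l; i <= res.off_r; ++i) {
    run += S[q[q0 + i] * 5 + r[r0 + i]];
    if (run > amax) { amax = run; aoff = i; }
  }
  res.anchor = aoff;
  return res;
}

// [[Rcpp::export]]
List gapless_extend_cpp(IntegerVector query, IntegerVector ref, int q0,
                        int r0, IntegerMatrix submat, int y) {
  int S[25];
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 5; ++j) S[i * 5 + j] = submat(i, j);
  GaplessRes g = gapless_core(query.begin(), query.size(), ref.begin(),
                              ref.size(), q0, r0, S, y);
  return List::create(
      _["query_start"] = q0 + g.off_l, _["ref_start"] = r0 + g.off_l,
      _["length"] = g.off_r - g.off_l + 1, _["score"] = g.score,
      _["anchor_query"] = q0 + g.anchor, _["anchor_ref"] = r0 + g.anchor);
}

// ---------------------------------------------------------------------------
// Gapped X-drop extension (affine gaps: a gap of length g costs
// gap_exist + gap_extend*g; adjacent insertions and deletions permitted).
// One direction; sequences are passed already oriented away from the anchor.
struct ExtRes { int score, qlen, rlen; std::string ops; };

// per-cell traceback byte: bits 0-1 predecessor state of M, 2-3 of Ix,
// 4-5 of Iy (state codes 0=M, 1=Ix consumes query, 2=Iy consumes ref)
static ExtRes xdrop_extend(const int* q, int qn, const int* r, int rn,
                           const int* S, int go, int ge, int ydrop,
                           bool want_ops) {
  ExtRes res{0, 0, 0, std::string()};
  if (qn == 0 && rn == 0) return res;
  int best = 0, bi = 0, bj = 0, bstate = 0;

  std::vector<int> Mp(rn + 1, NEG), Xp(rn + 1, NEG), Yp(rn + 1, NEG);
  std::vector<int> Mc(rn + 1, NEG), Xc(rn + 1, NEG), Yc(rn + 1, NEG);
  std::vector<std::vector<uint8_t>> dirs;
  std::vector<int> row_lo;
  int plo = 0, phi = 0;

  {  // row 0: leading gap in the query side (Iy) only
    Mp[0] = 0;
    std::vector<uint8_t> dr;
    if (want_ops) dr.push_back(0);
    int hi = 0;
    for (int j = 1; j <= rn; ++j) {
      int v = -(go + ge * j);
      if (v < best - ydrop) break;
      Yp[j] = v;
      if (want_ops) dr.push_back((uint8_t)((j == 1 ? 0 : 2) << 4));
      hi = j;
    }
    phi = hi;
    row_lo.push_back(0);
    dirs.push_back(dr);
  }

  int nrows = 0;
  for (int i = 1; i <= qn; ++i) {
    int lo = plo;
    int hi_limit = std::min(phi + 1, rn);
    std::vector<uint8_t> dr;
    int newlo = -1, newhi = -1;
    int touched_lo = lo, touched_hi = lo - 1;
    auto cell = [&](int j) -> bool {
      int m = NEG, x = NEG, yv = NEG;
      uint8_t db = 0;
      if (j >= 1) {
        int hm = Mp[j - 1], hx = Xp[j - 1], hy = Yp[j - 1];
        int h = std::max(hm, std::max(hx, hy));
        if (h > NEG / 2) {
          m = h + S[q[i - 1] * 5 + r[j - 1]];
          db |= (uint8_t)(h == hm ? 0 : (h == hx ? 1 : 2));
        }
      }
      {
        int hm = Mp[j], hx = Xp[j], hy = Yp[j];
        int open = std::max(hm, std::max(hx, hy));
        int ext = (hx > NEG / 2) ? hx - ge : NEG;
        int opn = (open > NEG / 2) ? open - (go + ge) : NEG;
        if (opn >= ext && opn > NEG / 2) {
          x = opn;
          db |= (uint8_t)((open == hm ? 0 : (open == hx ? 1 : 2)) << 2);
        } else if (ext > NEG / 2) {
          x = ext;
          db |= (uint8_t)(1 << 2);
        }
      }
      if (j >= 1) {
        int hm = Mc[j - 1], hx = Xc[j - 1], hy = Yc[j - 1];
        int open = std::max(hm, std::max(hx, hy));
        int ext = (hy > NEG / 2) ? hy - ge : NEG;
        int opn = (open > NEG / 2) ? open - (go + ge) : NEG;
        if (opn >= ext && opn > NEG / 2) {
          yv = opn;
          db |= (uint8_t)((open == hm ? 0 : (open == hx ? 1 : 2)) << 4);
        } else if (ext > NEG / 2) {
          yv = ext;
          db |= (uint8_t)(2 << 4);
        }
      }
      int h = std::max(m, std::max(x, yv));
      touched_hi = j;
      if (h < best - ydrop || h <= NEG / 2) {
        Mc[j] = Xc[j] = Yc[j] = NEG;
        if (want_ops) dr.push_back(0);
        return false;
      }
      Mc[j] = m; Xc[j] = x; Yc[j] = yv;
      if (want_ops) dr.push_back(db);
      if (h > best) {
        best = h; bi = i; bj = j;
        bstate = (h == m ? 0 : (h == x ? 1 : 2));
      }
      if (newlo < 0) newlo = j;
      newhi = j;
      return true;
    };
    int j = lo;
    for (; j <= hi_limit; ++j) cell(j);
    while (j <= rn) {           // keep extending right while Iy stays alive
      if (!cell(j)) break;
      ++j;
    }
    if (newlo < 0) break;  // whole row pruned: extension finished
    row_lo.push_back(lo);
    dirs.push_back(dr);
    nrows = i;
    // reset previous-row cells we will not overwrite next iteration
    Mp.swap(Mc); Xp.swap(Xc); Yp.swap(Yc);
    for (int jj = plo; jj <= phi; ++jj)
      if (jj < touched_lo || jj > touched_hi) Mc[jj] = Xc[jj] = Yc[jj] = NEG;
    for (int jj = touched_lo; jj <= touched_hi; ++jj)
      Mc[jj] = Xc[jj] = Yc[jj] = NEG;
    plo = newlo; phi = newhi;
    if (i > nrows) break;
  }

  res.score = best;
  res.qlen = bi;
  res.rlen = bj;
  if (want_ops && (bi > 0 || bj > 0)) {
    std::string ops;
    int i = bi, j = bj, st = bstate;
    while (i > 0 || j > 0) {
      uint8_t db = dirs[i][j - row_lo[i]];
      if (st == 0) { ops.push_back('M'); st = db & 3; --i; --j; }
      else if (st == 1) { ops.push_back('I'); st = (db >> 2) & 3; --i; }
      else { ops.push_back('D'); st = (db >> 4) & 3; --j; }
    }
    std::reverse(ops.begin(), ops.end());
    res.ops = ops;
  }
  return res;
}

struct GappedRec {
  int qs, qe, rs, re, score;
  std::string ops;
};

// Cap the reference-side extension length: a cell (i,j) can only stay
// within ydrop of the running maximum if j <= i*(1 + smax/ge) + ydrop/ge
// (score <= smax*i - go - ge*(j-i), best >= 0), so columns beyond the cap
// are provably dead.
static int ref_cap(int qn, int rn, const int* S, int ge, int ydrop) {
  int smax = 1;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) smax = std::max(smax, S[a * 5 + b]);
  double cap = (double)qn * (1.0 + (double)smax / ge) + (double)ydrop / ge + 2;
  if (cap > rn) cap = rn;
  return (int)cap;
}

static GappedRec gapped_core(const int* q, int qn, const int* r,
                             int rn, int qa, int ra, const int* S, int go,
                             int ge, int ydrop, bool want_ops) {
  int fq = qn - qa - 1, fr = rn - ra - 1;
  fr = ref_cap(fq, fr, S, ge, ydrop);
  ExtRes fwd = xdrop_extend(q + qa + 1, fq, r + ra + 1, fr, S, go, ge, ydrop,
                            want_ops);
  int br = ref_cap(qa, ra, S, ge, ydrop);
  std::vector<int> qr(qa), rr(br);
  for (int i = 0; i < qa; ++i) qr[i] = q[qa - 1 - i];
  for (int i = 0; i < br; ++i) rr[i] = r[ra - 1 - i];
  ExtRes bwd = xdrop_extend(qr.data(), qa, rr.data(), br, S, go, ge, ydrop,
                            want_ops);
  GappedRec rec;
  rec.score = S[q[qa] * 5 + r[ra]] + fwd.score + bwd.score;
  rec.qs = qa - bwd.qlen;
  rec.qe = qa + 1 + fwd.qlen;
  rec.rs = ra - bwd.rlen;
  rec.re = ra + 1 + fwd.rlen;
  if (want_ops) {
    std::string ops(bwd.ops.rbegin(), bwd.ops.rend());
    ops.push_back('M');
    ops += fwd.ops;
    rec.ops = ops;
  }
  return rec;
}

// [[Rcpp::export]]
List gapped_extend_cpp(IntegerVector query, IntegerVector ref, int anchor_q,
                       int anchor_r, IntegerMatrix submat, int gap_exist,
                       int gap_extend, int ydrop) {
  int S[25];
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 5; ++j) S[i * 5 + j] = submat(i, j);
  GappedRec rec = gapped_core(query.begin(), query.size(), ref.begin(),
                              ref.size(), anchor_q, anchor_r, S, gap_exist,
                              gap_extend, ydrop, true);
  return List::create(_["query_start"] = rec.qs, _["query_end"] = rec.qe,
                      _["ref_start"] = rec.rs, _["ref_end"] = rec.re,
                      _["score"] = rec.score, _["ops"] = rec.ops);
}

// ---------------------------------------------------------------------------
// Seed-and-extend pipeline for one query strand against one reference:
// adaptive seeds from every index -> canonical gapless extension per seed
// start column -> gapless score >= d -> gapped extension per distinct
// anchor -> records with score >= min_score.
// [[Rcpp::export]]
DataFrame align_core_cpp(IntegerVector query, IntegerVector ref, List sas,
                         List patterns, int m, int k, int y, int d, int ydrop,
                         IntegerMatrix submat, int gap_exist, int gap_extend,
                         int min_score, int maxdepth, bool want_ops) {
  int qn = query.size(), rn = ref.size();
  const int* qs = query.begin();
  const int* rs = ref.begin();
  int S[25];
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 5; ++j) S[i * 5 + j] = submat(i, j);

  std::unordered_set<long long> seen_cols, seen_anchors;
  std::vector<int> v_qs, v_qe, v_rs, v_re, v_sc;
  std::vector<std::string> v_ops;

  int npat = patterns.size();
  for (int p = 0; p < npat; ++p) {
    IntegerVector sa_in = sas[p];
    IntegerVector pattern = patterns[p];
    const int* sa = sa_in.begin();
    const int n_sa = sa_in.size();
    const int* pat = pattern.begin();
    int span = pattern.size();

    for (int q0 = 0; q0 < qn; q0 += k) {
      int lo = 0, hi = n_sa;
      for (int depth = 0; depth < maxdepth && q0 + depth < qn; ++depth) {
        int sym = pat[depth % span];
        int b = qs[q0 + depth];
        int qc;
        if (b >= 4) qc = -1;
        else if (sym == 2) qc = b;
        else if (sym == 1) qc = (b == 0 || b == 2) ? 0 : 1;
        else qc = 0;
        if (qc < 0) break;
        int l = lo, h = hi;
        while (l < h) {
          int mid = (l + h) / 2;
          int pos = sa[mid];
          int c;
          if (pos + depth >= rn || rs[pos + depth] >= 4) c = -1;
          else {
            int rb = rs[pos + depth];
            c = (sym == 2) ? rb : (sym == 1 ? ((rb == 0 || rb == 2) ? 0 : 1) : 0);
          }
          if (c < qc) l = mid + 1; else h = mid;
        }
        int nl = l;
        h = hi;
        while (l < h) {
          int mid = (l + h) / 2;
          int pos = sa[mid];
          int c;
          if (pos + depth >= rn || rs[pos + depth] >= 4) c = -1;
          else {
            int rb = rs[pos + depth];
            c = (sym == 2) ? rb : (sym == 1 ? ((rb == 0 || rb == 2) ? 0 : 1) : 0);
          }
          if (c <= qc) l = mid + 1; else h = mid;
        }
        lo = nl; hi = l;
        if (lo >= hi) break;
        if (hi - lo <= m) {
          for (int i = lo; i < hi; ++i) {
            int r0 = sa[i];
            long long key = (long long)q0 * rn + r0;
            if (!seen_cols.insert(key).second) continue;
            GaplessRes g = gapless_core(qs, qn, rs, rn, q0, r0, S, y);
            if (g.score < d) continue;
            int qa = q0 + g.anchor, ra = r0 + g.anchor;
            long long akey = (long long)qa * rn + ra;
            if (!seen_anchors.insert(akey).second) continue;
            GappedRec rec = gapped_core(qs, qn, rs, rn, qa, ra, S,
                                        gap_exist, gap_extend, ydrop,
                                        want_ops);
            if (rec.score < min_score) continue;
            v_qs.push_back(rec.qs); v_qe.push_back(rec.qe);
            v_rs.push_back(rec.rs); v_re.push_back(rec.re);
            v_sc.push_back(rec.score);
            v_ops.push_back(rec.ops);
          }
          break;
        }
      }
    }
  }
  return DataFrame::create(
      _["query_start"] = v_qs, _["query_end"] = v_qe, _["ref_start"] = v_rs,
      _["ref_end"] = v_re, _["score"] = v_sc, _["ops"] = wrap(v_ops),
      _["stringsAsFactors"] = false);
}
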