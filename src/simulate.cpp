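#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Mutates an ancestor sequence (codes 0..3) into a derived copy under an
// i.i.d. column model: substitution with probability p_sub, a substitution
// being a transition with probability ts_frac (A<->G, C<->T) else one of
// the two transversions; indel events occur before each ancestor position
// with probability indel_rate (insertion or deletion equally likely),
// lengths 1 + Geometric so the mean length is indel_len_mean. Uses R's RNG,
// so results are reproducible under set.seed(). Returns the two rows of the
// true alignment as gapped strings over ACGT- .
// [[Rcpp::export]]
List mutate_genome_cpp(IntegerVector ancestor, double p_sub, double ts_frac,
                       double indel_rate, double indel_len_mean) {
  static const char BASES[] = "ACGT";
  int n = ancestor.size();
  std::string ga, gd;
  ga.reserve((size_t)(n * 1.1) + 16);
  gd.reserve((size_t)(n * 1.1) + 16);
  double pgeom = 1.0 / std::max(1.0, indel_len_mean);
  int i = 0;
  while (i < n) {
    if (indel_rate > 0 && R::unif_rand() < indel_rate) {
      int g = 1 + (int)R::rgeom(pgeom);
      if (R::unif_rand() < 0.5) {  // insertion into the derived sequence
        for (int t = 0; t < g; ++t) {
          int b = (int)(R::unif_rand() * 4); if (b > 3) b = 3;
          ga.push_back('-');
          gd.push_back(BASES[b]);
        }
      } else {  // deletion of ancestor bases
        int del = std::min(g, n - i);
        for (int t = 0; t < del; ++t) {
          ga.push_back(BASES[ancestor[i + t]]);
          gd.push_back('-');
        }
        i += del;
        continue;
      }
    }
    int a = ancestor[i];
    int b = a;
    if (p_sub > 0 && R::unif_rand() < p_sub) {
      if (R::unif_rand() < ts_frac) {
        b = (a == 0) ? 2 : (a == 2) ? 0 : (a == 1) ? 3 : 1;  // transition
      } else {
        // one of the two transversions, equally likely
        int pick = (R::unif_rand() < 0.5) ? 0 : 1;
        if (a == 0) b = (pick == 0) ? 1 : 3;       // A -> C or T
        else if (a == 1) b = (pick == 0) ? 0 : 2;  // C -> A or G
        else if (a == 2) b = (pick == 0) ? 1 : 3;  // G -> C or T
        else b = (pick == 0) ? 0 : 2;              // T -> A or G
      }
    }
    ga.push_back(BASES[a]);
    gd.push_back(BASES[b]);
    ++i;
  }
  return List::create(_["ancestor_row"] = ga, _["derived_row"] = gd);
}
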