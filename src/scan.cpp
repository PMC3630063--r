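#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sliding-window minimum penalty sweep for target scanning.
//
// For every window start the minimum position-penalty score is computed
// for the three admissible window lengths: L (ungapped), L-1 (one miRNA
// base bulged) and L+1 (one target base bulged, charged at the following
// miRNA position). Weights: match 0, G:U 0.5, mismatch 1, gap 2, doubled
// at miRNA positions 2-13. Encoding: A=0, C=1, G=2, U=3.

static const double BIG = 1e18;

static inline double baseWeight(int a, int b) {
  bool wc = (a == 0 && b == 3) || (a == 3 && b == 0) ||
            (a == 2 && b == 1) || (a == 1 && b == 2);
  if (wc) return 0.0;
  bool gu = (a == 2 && b == 3) || (a == 3 && b == 2);
  return gu ? 0.5 : 1.0;
}

// [[Rcpp::export(name = ".scan_penalties_cpp")]]
List scan_penalties_cpp(IntegerVector mir, IntegerVector tx) {
  int L = mir.size();
  int n = tx.size();
  int nUn = std::max(0, n - L + 1);
  int nDel = std::max(0, n - L + 2);
  int nIns = std::max(0, n - L);
  NumericVector un(nUn), del(nDel), ins(nIns);
  if (n < L - 1) return List::create(_["un"] = un, _["del"] = del,
                                     _["ins"] = ins);
  std::vector<double> core(L + 2), gapw(L + 2);
  for (int i = 1; i <= L + 1; ++i) {
    core[i] = (i >= 2 && i <= 13) ? 2.0 : 1.0;
    gapw[i] = 2.0 * core[i];
  }
  std::vector<double> sufA(L + 2), preB(L + 1), preB2(L + 1);
  for (int s = 1; s <= nDel; ++s) {
    // A_i: miRNA i vs t[s + L - i]; B_i: t[s + L - i - 1];
    // B2_i: t[s + L - i + 1]   (all 1-based transcript indices)
    sufA[L + 1] = 0.0;
    for (int i = L; i >= 1; --i) {
      int idx = s + L - i;
      double a = (idx >= 1 && idx <= n) ?
        baseWeight(mir[i - 1], tx[idx - 1]) * core[i] : BIG;
      sufA[i] = std::min(BIG, sufA[i + 1] + a);
    }
    preB[0] = 0.0;
    preB2[0] = 0.0;
    for (int i = 1; i <= L; ++i) {
      int idxB = s + L - i - 1, idxB2 = s + L - i + 1;
      double b = (idxB >= 1 && idxB <= n) ?
        baseWeight(mir[i - 1], tx[idxB - 1]) * core[i] : BIG;
      double b2 = (idxB2 >= 1 && idxB2 <= n) ?
        baseWeight(mir[i - 1], tx[idxB2 - 1]) * core[i] : BIG;
      preB[i] = std::min(BIG, preB[i - 1] + b);
      preB2[i] = std::min(BIG, preB2[i - 1] + b2);
    }
    if (s <= nUn) un[s - 1] = sufA[1];
    double dbest = BIG;
    for (int g = 1; g <= L; ++g) {
      double v = gapw[g];
      if (g < L) v += sufA[g + 1];
      if (g > 1) v += preB[g - 1];
      if (v < dbest) dbest = v;
    }
    del[s - 1] = dbest;
    if (s <= nIns) {
      double ibest = BIG;
      for (int g = 1; g <= L - 1; ++g) {
        double v = gapw[g + 1] + sufA[g + 1] + preB2[g];
        if (v < ibest) ibest = v;
      }
      ins[s - 1] = ibest;
    }
  }
  return List::create(_["un"] = un, _["del"] = del, _["ins"] = ins);
}
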