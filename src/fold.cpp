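#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Stacking-only nested secondary structure model.
//
// Pair values (magnitudes; energies are negative): GC 3.0, AU 2.0, GU 1.0.
// A stack of two adjacent pairs (i,j)/(i+1,j-1) contributes
// -(value(i,j) + value(i+1,j-1)) / 2, so a run of identical pairs yields
// -value per stack and mixed stacks take the mean of the two pairs' values.
// Isolated pairs contribute 0. Minimum hairpin loop is 3 unpaired bases.

static const double INF = 1e9;
static const int MINLOOP = 3;

static inline double pairVal(int a, int b) {
  // encoding: A=0, C=1, G=2, U=3
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3.0; // G:C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2.0; // A:U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1.0; // G:U
  return 0.0;
}

struct FoldDP {
  int n;
  std::vector<int> s;
  std::vector<double> E; // E[i*n+j]: min energy of s[i..j]
  std::vector<double> P; // P[i*n+j]: min energy of s[i..j] with (i,j) paired

  double e(int i, int j) const { return (i > j || i < 0 || j >= n) ? 0.0 : E[i * n + j]; }
  double p(int i, int j) const { return P[i * n + j]; }

  bool canPair(int i, int j) const {
    return j - i - 1 >= MINLOOP && pairVal(s[i], s[j]) > 0.0;
  }

  // min energy of s[a..b] among structures where (a,b) are NOT paired together
  double enp(int a, int b) const {
    if (b - a + 1 < 2) return 0.0;
    double best = e(a, b - 1); // b unpaired
    for (int k = a + 1; k <= b - MINLOOP - 1; ++k) {
      if (canPair(k, b) && p(k, b) < INF) {
        double v = e(a, k - 1) + p(k, b);
        if (v < best) best = v;
      }
    }
    return best;
  }

  void run(const std::vector<int>& seq) {
    s = seq;
    n = (int)s.size();
    E.assign((size_t)n * n, 0.0);
    P.assign((size_t)n * n, INF);
    for (int len = MINLOOP + 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        if (canPair(i, j)) {
          double best = enp(i + 1, j - 1); // interior not stacked on (i,j)
          if (canPair(i + 1, j - 1) && p(i + 1, j - 1) < INF) {
            double st = p(i + 1, j - 1) -
              (pairVal(s[i], s[j]) + pairVal(s[i + 1], s[j - 1])) / 2.0;
            if (st < best) best = st;
          }
          P[i * n + j] = best;
        }
        // E recursion: j unpaired, or j paired to some k >= i.
        // Ties are resolved in the traceback, which prefers the pairing
        // whose 5' index is smallest.
        double best = e(i, j - 1);
        for (int k = i; k <= j - MINLOOP - 1; ++k) {
          if (canPair(k, j) && p(k, j) < INF) {
            double v = e(i, k - 1) + p(k, j);
            if (v < best) best = v;
          }
        }
        E[i * n + j] = best;
      }
    }
  }

  void traceE(int i, int j, std::string& db) const;
  void traceP(int i, int j, std::string& db) const;
  void traceEnp(int a, int b, std::string& db) const;
};

void FoldDP::traceE(int i, int j, std::string& db) const {
  if (j - i + 1 < MINLOOP + 2) return;
  double target = e(i, j);
  // prefer the decomposition pairing the smallest 5' index k with j
  for (int k = i; k <= j - MINLOOP - 1; ++k) {
    if (canPair(k, j) && p(k, j) < INF &&
        std::abs(e(i, k - 1) + p(k, j) - target) < 1e-9) {
      traceE(i, k - 1, db);
      traceP(k, j, db);
      return;
    }
  }
  traceE(i, j - 1, db); // j unpaired
}

void FoldDP::traceP(int i, int j, std::string& db) const {
  db[i] = '(';
  db[j] = ')';
  double target = p(i, j);
  if (canPair(i + 1, j - 1) && p(i + 1, j - 1) < INF) {
    double st = p(i + 1, j - 1) -
      (pairVal(s[i], s[j]) + pairVal(s[i + 1], s[j - 1])) / 2.0;
    if (std::abs(st - target) < 1e-9) { traceP(i + 1, j - 1, db); return; }
  }
  traceEnp(i + 1, j - 1, db);
}

void FoldDP::traceEnp(int a, int b, std::string& db) const {
  if (b - a + 1 < 2) return;
  double target = enp(a, b);
  for (int k = a + 1; k <= b - MINLOOP - 1; ++k) {
    if (canPair(k, b) && p(k, b) < INF &&
        std::abs(e(a, k - 1) + p(k, b) - target) < 1e-9) {
      traceE(a, k - 1, db);
      traceP(k, b, db);
      return;
    }
  }
  traceE(a, b - 1, db);
}

// [[Rcpp::export(name = ".fold_rna_cpp")]]
List fold_rna_cpp(IntegerVector seq) {
  int n = seq.size();
  std::string db(n, '.');
  if (n < MINLOOP + 2) return List::create(_["structure"] = db, _["mfe"] = 0.0);
  FoldDP dp;
  dp.run(std::vector<int>(seq.begin(), seq.end()));
  double mfe = dp.e(0, n - 1);
  if (mfe > 0.0) mfe = 0.0;
  dp.traceE(0, n - 1, db);
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}
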