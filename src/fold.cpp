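#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Minimum-free-energy folding under a simplified stacking energy model.
//
// Structure energy is a sum over pairs (i,j):
//   - interior empty (hairpin loop, >= 3 unpaired): +E_HAIRPIN
//   - (i+1,j-1) also paired to each other (stack):  -(s(i,j)+s(i+1,j-1))/2
//   - interior holds pairs but not (i+1,j-1):       +E_INTERNAL
// with pair strengths s(GC)=3.4, s(AU)=2.2, s(GU)=1.4 kcal/mol.
// The same function of a structure is evaluated directly by the R-level
// enumeration oracle; this DP finds its minimum.

static const double INF = std::numeric_limits<double>::infinity();
static const int MINLOOP = 3;

static double pair_strength(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3.4;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2.2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1.4;
  return 0.0;
}
static bool can_pair(char a, char b) { return pair_strength(a, b) > 0.0; }

struct FoldDP {
  int n;
  const std::string &s;
  double E_HAIRPIN, E_INTERNAL;
  std::vector<double> V, W, Wp, X; // n*n, index i*n+j
  FoldDP(const std::string &seq, double hp, double ip) : n(seq.size()), s(seq),
    E_HAIRPIN(hp), E_INTERNAL(ip),
    V(n * n, INF), W(n * n, 0.0), Wp(n * n, INF), X(n * n, INF) {}
  inline double &v(int i, int j) { return V[i * n + j]; }
  inline double &w(int i, int j) { return W[i * n + j]; }
  inline double &wp(int i, int j) { return Wp[i * n + j]; }
  inline double &x(int i, int j) { return X[i * n + j]; }
  inline double getW(int i, int j) { return (i > j) ? 0.0 : w(i, j); }

  void run() {
    for (int span = MINLOOP + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // V(i,j)
        if (can_pair(s[i], s[j]) && j - i - 1 >= MINLOOP) {
          double best = E_HAIRPIN;
          if (v(i + 1, j - 1) < INF && can_pair(s[i + 1], s[j - 1])) {
            double stk = -(pair_strength(s[i], s[j]) +
                           pair_strength(s[i + 1], s[j - 1])) / 2.0;
            best = std::min(best, stk + v(i + 1, j - 1));
          }
          if (x(i + 1, j - 1) < INF)
            best = std::min(best, E_INTERNAL + x(i + 1, j - 1));
          v(i, j) = best;
        }
        // Wp(i,j): >= 1 pair somewhere in [i,j]
        double b = (i + 1 <= j) ? wp(i + 1, j) : INF;
        for (int k = i + MINLOOP + 1; k <= j; ++k)
          if (v(i, k) < INF) b = std::min(b, v(i, k) + getW(k + 1, j));
        wp(i, j) = b;
        // X(i,j): >= 1 pair, but (i,j) not paired to each other
        double bx = (i + 1 <= j) ? wp(i + 1, j) : INF;
        for (int k = i + MINLOOP + 1; k < j; ++k)
          if (v(i, k) < INF) bx = std::min(bx, v(i, k) + getW(k + 1, j));
        x(i, j) = bx;
        // W(i,j)
        w(i, j) = std::min(0.0, wp(i, j));
      }
    }
  }

  void traceW(int i, int j, std::vector<int> &pair);
  void traceWp(int i, int j, std::vector<int> &pair);
  void traceX(int i, int j, std::vector<int> &pair);
  void traceV(int i, int j, std::vector<int> &pair);
};

void FoldDP::traceW(int i, int j, std::vector<int> &pair) {
  if (i >= j) return;
  if (wp(i, j) < 0.0) traceWp(i, j, pair);
}
void FoldDP::traceWp(int i, int j, std::vector<int> &pair) {
  if (i >= j) return;
  if (i + 1 <= j && wp(i, j) == wp(i + 1, j)) { traceWp(i + 1, j, pair); return; }
  for (int k = i + MINLOOP + 1; k <= j; ++k) {
    if (v(i, k) < INF && v(i, k) + getW(k + 1, j) == wp(i, j)) {
      traceV(i, k, pair);
      if (k + 1 <= j) traceW(k + 1, j, pair);
      return;
    }
  }
}
void FoldDP::traceX(int i, int j, std::vector<int> &pair) {
  if (i >= j) return;
  if (i + 1 <= j && x(i, j) == wp(i + 1, j)) { traceWp(i + 1, j, pair); return; }
  for (int k = i + MINLOOP + 1; k < j; ++k) {
    if (v(i, k) < INF && v(i, k) + getW(k + 1, j) == x(i, j)) {
      traceV(i, k, pair);
      if (k + 1 <= j) traceW(k + 1, j, pair);
      return;
    }
  }
}
void FoldDP::traceV(int i, int j, std::vector<int> &pair) {
  pair[i] = j; pair[j] = i;
  if (v(i, j) == E_HAIRPIN) return;
  if (v(i + 1, j - 1) < INF && can_pair(s[i + 1], s[j - 1])) {
    double stk = -(pair_strength(s[i], s[j]) +
                   pair_strength(s[i + 1], s[j - 1])) / 2.0;
    if (v(i, j) == stk + v(i + 1, j - 1)) { traceV(i + 1, j - 1, pair); return; }
  }
  if (x(i + 1, j - 1) < INF && v(i, j) == E_INTERNAL + x(i + 1, j - 1))
    traceX(i + 1, j - 1, pair);
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, double hairpin_penalty, double internal_penalty) {
  int n = seq.size();
  if (n == 0) return List::create(Named("mfe") = 0.0,
                                  Named("pairs") = IntegerVector(0));
  FoldDP dp(seq, hairpin_penalty, internal_penalty);
  dp.run();
  double mfe = (n >= 2) ? dp.getW(0, n - 1) : 0.0;
  std::vector<int> pair(n, -1);
  if (mfe < 0.0) dp.traceW(0, n - 1, pair);
  else mfe = 0.0;
  IntegerVector p(n);
  for (int i = 0; i < n; ++i) p[i] = pair[i] + 1; // 1-based, 0 = unpaired
  return List::create(Named("mfe") = mfe, Named("pairs") = p);
}
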