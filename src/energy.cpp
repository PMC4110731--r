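// Nearest-neighbor duplex hybridization and constrained-folding MFE engines.
//
// Nucleotide encoding: A=1, C=2, G=3, U=4, N=5 (N never pairs).
// Pair types: AU=1, UA=2, GC=3, CG=4, GU=5, UG=6; 0 = not pairable.
// Stack matrices are 6x6, indexed (pair_type - 1) for the 5' pair of the
// stack on the rows and the 3' pair on the columns.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = 1e9;

static inline int pair_type(int x, int y) {
  if (x == 1 && y == 4) return 1;  // A:U
  if (x == 4 && y == 1) return 2;  // U:A
  if (x == 3 && y == 2) return 3;  // G:C
  if (x == 2 && y == 3) return 4;  // C:G
  if (x == 3 && y == 4) return 5;  // G:U
  if (x == 4 && y == 3) return 6;  // U:G
  return 0;
}

// Loop term between consecutive duplex pairs with a unpaired nucleotides on
// one strand and b on the other (a = b = 0 means a stack, handled by caller).
static inline double gap_penalty(int a, int b, double bulge_open,
                                 double bulge_ext, double il_open,
                                 double il_ext) {
  if (a == 0 || b == 0) return bulge_open + bulge_ext * (a + b);
  return il_open + il_ext * (a + b);
}

// Minimum free energy of the intermolecular duplex between mi and tg
// (both 5'->3', antiparallel pairing, intramolecular pairs forbidden).
// The empty duplex has energy 0, so the result is never positive.
// [[Rcpp::export]]
double duplex_mfe_cpp(IntegerVector mi, IntegerVector tg, NumericMatrix stacks,
                      double init, double bulge_open, double bulge_ext,
                      double il_open, double il_ext) {
  int m = mi.size(), n = tg.size();
  if (m < 1 || n < 1) stop("empty sequence");
  // H(i, j): best energy of a duplex whose 3'-most (on mi) pair is (i, j),
  // excluding the initiation term.
  std::vector<std::vector<double> > H(m, std::vector<double>(n, INF));
  std::vector<std::vector<int> > pt(m, std::vector<int>(n, 0));
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) pt[i][j] = pair_type(mi[i], tg[j]);
  double best = 0.0;  // empty duplex
  for (int i = 0; i < m; ++i) {
    for (int j = n - 1; j >= 0; --j) {
      if (!pt[i][j]) continue;
      double h = 0.0;  // (i, j) is the first pair
      for (int ip = 0; ip < i; ++ip) {
        for (int jp = n - 1; jp > j; --jp) {
          if (!pt[ip][jp] || H[ip][jp] >= INF) continue;
          int a = i - ip - 1, b = jp - j - 1;
          double term;
          if (a == 0 && b == 0)
            term = stacks(pt[ip][jp] - 1, pt[i][j] - 1);
          else
            term = gap_penalty(a, b, bulge_open, bulge_ext, il_open, il_ext);
          double cand = H[ip][jp] + term;
          if (cand < h) h = cand;
        }
      }
      H[i][j] = h;
      if (init + h < best) best = init + h;
    }
  }
  return best;
}

// Intramolecular MFE of s under a linear-loop nearest-neighbor model:
// stacks from the table, hairpins (min loop 3) and bulge/interior loops with
// affine size penalties, multiloops affine in branches and unpaired bases.
// Positions with forced[i] == TRUE may not pair.  Empty structure = 0.
// [[Rcpp::export]]
double fold_mfe_cpp(IntegerVector s, NumericMatrix stacks, double hp_open,
                    double hp_ext, double bulge_open, double bulge_ext,
                    double il_open, double il_ext, double ml_open,
                    double ml_branch, double ml_unpaired,
                    LogicalVector forced) {
  int n = s.size();
  if (n == 0) return 0.0;
  if (forced.size() != n) stop("constraint mask length mismatch");
  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
  std::vector<std::vector<double> > M(n, std::vector<double>(n, INF));
  std::vector<std::vector<int> > pt(n, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (!forced[i] && !forced[j]) pt[i][j] = pair_type(s[i], s[j]);

  for (int len = 5; len <= n; ++len) {       // j - i + 1; min hairpin loop 3
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      if (pt[i][j]) {
        double v = hp_open + hp_ext * (j - i - 1);  // hairpin closure
        for (int p = i + 1; p < j - 1; ++p) {
          for (int q = j - 1; q > p; --q) {
            if (!pt[p][q] || V[p][q] >= INF) continue;
            int a = p - i - 1, b = j - q - 1;
            double term;
            if (a == 0 && b == 0)
              term = stacks(pt[i][j] - 1, pt[p][q] - 1);
            else
              term = gap_penalty(a, b, bulge_open, bulge_ext, il_open, il_ext);
            double cand = V[p][q] + term;
            if (cand < v) v = cand;
          }
        }
        // multiloop: >= 2 branches strictly inside (i, j)
        for (int k = i + 1; k < j - 1; ++k) {
          if (M[i + 1][k] >= INF || M[k + 1][j - 1] >= INF) continue;
          double cand = ml_open + ml_branch + M[i + 1][k] + M[k + 1][j - 1];
          if (cand < v) v = cand;
        }
        V[i][j] = v;
      }
      // M(i, j): >= 1 multiloop branch in [i, j], unpaired bases charged.
      double mm = INF;
      if (pt[i][j] && V[i][j] < INF) mm = V[i][j] + ml_branch;
      if (j > i && M[i][j - 1] < INF) {
        double cand = M[i][j - 1] + ml_unpaired;
        if (cand < mm) mm = cand;
      }
      if (j > i && M[i + 1][j] < INF) {
        double cand = M[i + 1][j] + ml_unpaired;
        if (cand < mm) mm = cand;
      }
      for (int k = i; k < j; ++k) {
        if (M[i][k] >= INF || M[k + 1][j] >= INF) continue;
        double cand = M[i][k] + M[k + 1][j];
        if (cand < mm) mm = cand;
      }
      M[i][j] = mm;
    }
  }

  // external loop: unpaired bases free
  std::vector<double> W(n + 1, 0.0);
  for (int j = 0; j < n; ++j) {
    W[j + 1] = W[j];
    for (int i = 0; i <= j; ++i) {
      if (!pt[i][j] || V[i][j] >= INF) continue;
      double cand = W[i] + V[i][j];
      if (cand < W[j + 1]) W[j + 1] = cand;
    }
  }
  return W[n];
}
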