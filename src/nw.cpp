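#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Gotoh three-state global alignment with affine gaps.
// States: 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y (gap in a, consumes b).
// A gap of length L costs open + (L - 1) * extend (open and extend are negative scores).
// Tie-breaks are fixed to M > X > Y everywhere so the traceback is deterministic:
// prefer diagonal, then up (gap in target), then left.

static inline int best3(double m, double x, double y, double &out) {
  // returns the arg state under the M > X > Y preference order
  int s = 0;
  out = m;
  if (x > out) { out = x; s = 1; }
  if (y > out) { out = y; s = 2; }
  return s;
}

// [[Rcpp::export(name = ".nw_align_c")]]
List nw_align_c(IntegerVector a, IntegerVector b, NumericMatrix S,
                double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  // scores and predecessor-state pointers, (n+1) x (m+1), column-major index
  std::vector<double> M((n + 1) * (m + 1), NEG), X = M, Y = M;
  std::vector<signed char> pM((n + 1) * (m + 1), -1), pX = pM, pY = pM;
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gap_open + (i - 1) * gap_extend;
    pX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gap_open + (j - 1) * gap_extend;
    pY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = S(a[i - 1] - 1, b[j - 1] - 1);
      double sc;
      int st = best3(M[at(i - 1, j - 1)], X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)], sc);
      M[at(i, j)] = s + sc;
      pM[at(i, j)] = (signed char)st;

      st = best3(M[at(i - 1, j)] + gap_open,
                 X[at(i - 1, j)] + gap_extend,
                 Y[at(i - 1, j)] + gap_open, sc);
      X[at(i, j)] = sc;
      pX[at(i, j)] = (signed char)st;

      st = best3(M[at(i, j - 1)] + gap_open,
                 X[at(i, j - 1)] + gap_open,
                 Y[at(i, j - 1)] + gap_extend, sc);
      Y[at(i, j)] = sc;
      pY[at(i, j)] = (signed char)st;
    }
  }

  double score;
  int state = best3(M[at(n, m)], X[at(n, m)], Y[at(n, m)], score);

  // traceback: moves coded 1 = diagonal, 2 = up (gap in b), 3 = left (gap in a)
  std::vector<int> moves;
  moves.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev;
    if (state == 0) {
      prev = pM[at(i, j)];
      moves.push_back(1);
      --i; --j;
    } else if (state == 1) {
      prev = pX[at(i, j)];
      moves.push_back(2);
      --i;
    } else {
      prev = pY[at(i, j)];
      moves.push_back(3);
      --j;
    }
    state = prev;
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = score,
                      _["moves"] = IntegerVector(moves.begin(), moves.end()));
}
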