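// Needleman-Wunsch global alignment with affine gaps, for residue index
// vectors (scored through a substitution matrix) and for pre-scored
// profile-profile column score matrices.  Gap of length L costs
// gap_open + gap_extend * L.  Tie-breaking is deterministic: diagonal,
// then up (gap in b), then left (gap in a).

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

// core DP over a precomputed cell score matrix sc (n x m);
// returns moves (1 = diag, 2 = up/consume row, 3 = left/consume col) and score
static List nw_core(const NumericMatrix& sc, double go, double ge) {
  const int n = sc.nrow(), m = sc.ncol();
  const double open = go + ge;   // first gap position
  // M: end in match; X: end in gap consuming rows; Y: gap consuming cols
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  std::vector<signed char> tbM((n + 1) * (m + 1), 0),
      tbX((n + 1) * (m + 1), 0), tbY((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(go + ge * i);
    tbX[at(i, 0)] = 2;  // extend
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -(go + ge * j);
    tbY[at(0, j)] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M from any of M/X/Y diag; preference M > X > Y
      double d0 = M[at(i - 1, j - 1)], d1 = X[at(i - 1, j - 1)],
             d2 = Y[at(i - 1, j - 1)];
      double dm = d0; signed char tm = 0;
      if (d1 > dm) { dm = d1; tm = 1; }
      if (d2 > dm) { dm = d2; tm = 2; }
      M[at(i, j)] = dm + sc(i - 1, j - 1);
      tbM[at(i, j)] = tm;
      // X: gap consuming row i; open from M/Y, extend from X
      double xo = std::max(M[at(i - 1, j)], Y[at(i - 1, j)]) - open;
      double xe = X[at(i - 1, j)] - ge;
      bool x_open = M[at(i - 1, j)] >= Y[at(i - 1, j)];
      if (xo >= xe) { X[at(i, j)] = xo; tbX[at(i, j)] = x_open ? 0 : 3; }
      else          { X[at(i, j)] = xe; tbX[at(i, j)] = 2; }
      // Y: gap consuming col j
      double yo = std::max(M[at(i, j - 1)], X[at(i, j - 1)]) - open;
      double ye = Y[at(i, j - 1)] - ge;
      bool y_open = M[at(i, j - 1)] >= X[at(i, j - 1)];
      if (yo >= ye) { Y[at(i, j)] = yo; tbY[at(i, j)] = y_open ? 0 : 3; }
      else          { Y[at(i, j)] = ye; tbY[at(i, j)] = 2; }
    }
  }
  double best = M[at(n, m)];
  int state = 0;  // 0 = M, 1 = X, 2 = Y ; preference M > X > Y
  if (X[at(n, m)] > best) { best = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > best) { best = Y[at(n, m)]; state = 2; }

  std::vector<int> moves;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char t = tbM[at(i, j)];
      moves.push_back(1);
      --i; --j;
      state = (t == 0) ? 0 : (t == 1 ? 1 : 2);
    } else if (state == 1) {
      signed char t = tbX[at(i, j)];
      moves.push_back(2);
      --i;
      state = (t == 2) ? 1 : (t == 0 ? 0 : 2);
    } else {
      signed char t = tbY[at(i, j)];
      moves.push_back(3);
      --j;
      state = (t == 2) ? 2 : (t == 0 ? 0 : 1);
    }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = best, _["moves"] = wrap(moves));
}

// [[Rcpp::export]]
List cpp_nw_align(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_extend) {
  NumericMatrix sc(a.size(), b.size());
  for (int i = 0; i < a.size(); ++i)
    for (int j = 0; j < b.size(); ++j)
      sc(i, j) = S(a[i], b[j]);
  return nw_core(sc, gap_open, gap_extend);
}

// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix colscore, double gap_open,
                       double gap_extend) {
  return nw_core(colscore, gap_open, gap_extend);
}
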