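#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// dynamic program. A gap of length L costs gap_open + L * gap_extend.
// Deterministic tie-breaking in the traceback: on equal score prefer a
// match/mismatch column, then a gap in the first sequence (consuming the
// second), then a gap in the second sequence; the same priority applies when
// choosing the predecessor state.
//
// States: 0 = M (both consumed), 1 = Y (gap in a), 2 = X (gap in b).

static const double NEG_INF = -1e300;
static const double TIE_TOL = 1e-9;

// [[Rcpp::export]]
List nw_affine_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                   double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  double go = gap_open + gap_extend;  // cost of a gap's first residue
  double ge = gap_extend;

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  M(0, 0) = 0.0;
  X(0, 0) = NEG_INF;
  Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF;
    Y(i, 0) = NEG_INF;
    X(i, 0) = -(gap_open + i * gap_extend);
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = -(gap_open + j * gap_extend);
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(a[i - 1], b[j - 1]);
      double dM = M(i - 1, j - 1), dY = Y(i - 1, j - 1), dX = X(i - 1, j - 1);
      double best = dM;
      if (dY > best) best = dY;
      if (dX > best) best = dX;
      M(i, j) = best + s;
      double xm = M(i - 1, j) - go, xy = Y(i - 1, j) - go,
             xx = X(i - 1, j) - ge;
      double xbest = xm;
      if (xy > xbest) xbest = xy;
      if (xx > xbest) xbest = xx;
      X(i, j) = xbest;
      double ym = M(i, j - 1) - go, yx = X(i, j - 1) - go,
             yy = Y(i, j - 1) - ge;
      double ybest = ym;
      if (yx > ybest) ybest = yx;
      if (yy > ybest) ybest = yy;
      Y(i, j) = ybest;
    }
  }

  double score = M(n, m);
  int state = 0;  // priority M > Y > X
  if (Y(n, m) > score + TIE_TOL) { score = Y(n, m); state = 1; }
  if (X(n, m) > score + TIE_TOL) { score = X(n, m); state = 2; }

  std::string ga, gb;
  ga.reserve(n + m);
  gb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 1;
    else if (j == 0) state = 2;
    if (state == 0) {
      double s = sub(a[i - 1], b[j - 1]);
      double target = M(i, j) - s;
      ga.push_back((char)(a[i - 1]));
      gb.push_back((char)(b[j - 1]));
      int prev;
      if (std::abs(M(i - 1, j - 1) - target) < TIE_TOL) prev = 0;
      else if (std::abs(Y(i - 1, j - 1) - target) < TIE_TOL) prev = 1;
      else prev = 2;
      --i; --j;
      state = prev;
    } else if (state == 1) {  // gap in a, consume b
      double target = Y(i, j);
      ga.push_back((char)255);
      gb.push_back((char)(b[j - 1]));
      int prev;
      if (j >= 1 && std::abs(M(i, j - 1) - go - target) < TIE_TOL) prev = 0;
      else if (j >= 1 && std::abs(Y(i, j - 1) - ge - target) < TIE_TOL) prev = 1;
      else prev = 2;
      --j;
      state = prev;
    } else {  // gap in b, consume a
      double target = X(i, j);
      ga.push_back((char)(a[i - 1]));
      gb.push_back((char)255);
      int prev;
      if (i >= 1 && std::abs(M(i - 1, j) - go - target) < TIE_TOL) prev = 0;
      else if (i >= 1 && std::abs(Y(i - 1, j) - go - target) < TIE_TOL) prev = 1;
      else prev = 2;
      --i;
      state = prev;
    }
  }
  // emitted back-to-front; translate indices to 0-based ints, 255 = gap
  int L = ga.size();
  IntegerVector ai(L), bi(L);
  for (int k = 0; k < L; ++k) {
    unsigned char ca = (unsigned char)ga[L - 1 - k];
    unsigned char cb = (unsigned char)gb[L - 1 - k];
    ai[k] = (ca == 255) ? NA_INTEGER : (int)ca;
    bi[k] = (cb == 255) ? NA_INTEGER : (int)cb;
  }
  return List::create(_["score"] = score, _["a_idx"] = ai, _["b_idx"] = bi);
}
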