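#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps.
// A gap of length L costs gap_open + L * gap_ext (both ends penalized).
// Three-state DP (M = aligned pair, X = gap in b consuming a, Y = gap in
// a consuming b) with deterministic tie-breaking on traceback:
// prefer M, then Y (gap in a), then X (gap in b).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// pick best of (m, x, y) with preference M > Y > X on ties
static inline int pick_state(double m, double x, double y) {
  double best = m;
  int state = 0;
  if (y > best) { best = y; state = 2; }
  if (x > best) { best = x; state = 1; }
  return state;
}

// [[Rcpp::export(name = ".nw_affine")]]
List nw_affine(IntegerVector a, IntegerVector b, NumericMatrix submat,
               double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const double og = gap_open + gap_ext;  // cost of a gap's first position
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: predecessor state (0=M, 1=X, 2=Y)
  std::vector<signed char> tbM((n + 1) * W, -1), tbX((n + 1) * W, -1),
      tbY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(gap_open + i * gap_ext);
    tbX[i * W] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(gap_open + j * gap_ext);
    tbY[j] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      // M: align a_i with b_j
      int sM = pick_state(M[d], X[d], Y[d]);
      double vM = (sM == 0 ? M[d] : (sM == 1 ? X[d] : Y[d]));
      if (vM > NEG_INF) {
        M[c] = vM + submat(ai, b[j - 1]);
        tbM[c] = (signed char)sM;
      }
      // X: gap in b (consume a_i)
      {
        double fromM = (M[up] > NEG_INF) ? M[up] - og : NEG_INF;
        double fromX = (X[up] > NEG_INF) ? X[up] - gap_ext : NEG_INF;
        double fromY = (Y[up] > NEG_INF) ? Y[up] - og : NEG_INF;
        int s = pick_state(fromM, fromX, fromY);
        double v = (s == 0 ? fromM : (s == 1 ? fromX : fromY));
        if (v > NEG_INF) { X[c] = v; tbX[c] = (signed char)s; }
      }
      // Y: gap in a (consume b_j)
      {
        double fromM = (M[lf] > NEG_INF) ? M[lf] - og : NEG_INF;
        double fromX = (X[lf] > NEG_INF) ? X[lf] - og : NEG_INF;
        double fromY = (Y[lf] > NEG_INF) ? Y[lf] - gap_ext : NEG_INF;
        int s = pick_state(fromM, fromX, fromY);
        double v = (s == 0 ? fromM : (s == 1 ? fromX : fromY));
        if (v > NEG_INF) { Y[c] = v; tbY[c] = (signed char)s; }
      }
    }
  }

  const int end = n * W + m;
  int state = pick_state(M[end], X[end], Y[end]);
  double score = (state == 0 ? M[end] : (state == 1 ? X[end] : Y[end]));

  // traceback (codes are 0-based rows of submat; -1 marks a gap)
  std::vector<int> al_a, al_b;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      int prev = tbM[c];
      al_a.push_back(a[i - 1]);
      al_b.push_back(b[j - 1]);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      int prev = tbX[c];
      al_a.push_back(a[i - 1]);
      al_b.push_back(-1);
      --i;
      state = prev;
    } else {
      int prev = tbY[c];
      al_a.push_back(-1);
      al_b.push_back(b[j - 1]);
      --j;
      state = prev;
    }
  }
  std::reverse(al_a.begin(), al_a.end());
  std::reverse(al_b.begin(), al_b.end());

  int matches = 0;
  for (size_t k = 0; k < al_a.size(); ++k) {
    if (al_a[k] >= 0 && al_a[k] == al_b[k]) ++matches;
  }
  return List::create(_["score"] = score,
                      _["aligned_a_codes"] = IntegerVector(al_a.begin(), al_a.end()),
                      _["aligned_b_codes"] = IntegerVector(al_b.begin(), al_b.end()),
                      _["matches"] = matches,
                      _["align_length"] = (int)al_a.size());
}
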