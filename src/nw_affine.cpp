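// Global pairwise alignment with affine gap costs (Gotoh), used by the
// built-in center-star segment realigner. A gap of length k costs
// open + k * extend. Tie-breaks are deterministic: diagonal, then up
// (gap in b), then left (gap in a), and within a gap state continuing the
// gap is preferred over reopening from another state of equal score.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -1e30;

// a, b: 1-based indices into the substitution matrix S.
// Returns list(score, a_idx, b_idx): equal-length vectors over the aligned
// columns, 0 marking a gap.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double open, double ext) {
  const int n = a.size(), m = b.size();
  const double gopen = open + ext;  // cost of the first gap position

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);  // gap in b (consumes a)
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);  // gap in a (consumes b)
  // traceback: which predecessor state (0=M, 1=X, 2=Y, -1 none)
  std::vector<signed char> tbM((n + 1) * (m + 1), -1);
  std::vector<signed char> tbX((n + 1) * (m + 1), -1);
  std::vector<signed char> tbY((n + 1) * (m + 1), -1);

  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(open + ext * i);
    tbX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -(open + ext * j);
    tbY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const double s_ai = 0.0;  // silence unused warnings
    (void)s_ai;
    for (int j = 1; j <= m; ++j) {
      const double sub = S(a[i - 1] - 1, b[j - 1] - 1);
      // M: diagonal from best of the three states
      double best = M[at(i - 1, j - 1)];
      signed char who = 0;
      if (X[at(i - 1, j - 1)] > best) { best = X[at(i - 1, j - 1)]; who = 1; }
      if (Y[at(i - 1, j - 1)] > best) { best = Y[at(i - 1, j - 1)]; who = 2; }
      if (best > NEG_INF / 2) {
        M[at(i, j)] = best + sub;
        tbM[at(i, j)] = who;
      }
      // X: gap in b, consume a[i] (move up). Prefer M-open, then X-extend,
      // then Y-open on ties (diagonal-first spirit: reopening from M wins).
      double vm = M[at(i - 1, j)] > NEG_INF / 2 ? M[at(i - 1, j)] - gopen : NEG_INF;
      double vx = X[at(i - 1, j)] > NEG_INF / 2 ? X[at(i - 1, j)] - ext : NEG_INF;
      double vy = Y[at(i - 1, j)] > NEG_INF / 2 ? Y[at(i - 1, j)] - gopen : NEG_INF;
      best = vm; who = 0;
      if (vx > best) { best = vx; who = 1; }
      if (vy > best) { best = vy; who = 2; }
      if (best > NEG_INF / 2) { X[at(i, j)] = best; tbX[at(i, j)] = who; }
      // Y: gap in a, consume b[j] (move left)
      vm = M[at(i, j - 1)] > NEG_INF / 2 ? M[at(i, j - 1)] - gopen : NEG_INF;
      vx = X[at(i, j - 1)] > NEG_INF / 2 ? X[at(i, j - 1)] - gopen : NEG_INF;
      vy = Y[at(i, j - 1)] > NEG_INF / 2 ? Y[at(i, j - 1)] - ext : NEG_INF;
      best = vm; who = 0;
      if (vx > best) { best = vx; who = 1; }
      if (vy > best) { best = vy; who = 2; }
      if (best > NEG_INF / 2) { Y[at(i, j)] = best; tbY[at(i, j)] = who; }
    }
  }

  // final state: prefer M, then X (up), then Y (left)
  int state = 0;
  double score = M[at(n, m)];
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 2; }

  std::vector<int> ai, bi;
  ai.reserve(n + m);
  bi.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char prev = tbM[at(i, j)];
      ai.push_back(i); bi.push_back(j);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      signed char prev = tbX[at(i, j)];
      ai.push_back(i); bi.push_back(0);
      --i;
      state = prev;
    } else {
      signed char prev = tbY[at(i, j)];
      ai.push_back(0); bi.push_back(j);
      --j;
      state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["score"] = score,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi.begin(), bi.end()));
}
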