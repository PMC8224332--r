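#include <Rcpp.h>
using namespace Rcpp;

// Global (end-gap penalised) affine-gap alignment over a precomputed
// column-vs-column score matrix, so the same kernel serves both pairwise
// sequence alignment and profile-profile alignment during progressive MSA.
//
// Gap cost model: a gap of length L costs gap_open + (L - 1) * gap_extend
// (both negative). Tie-break in the traceback is diagonal > up > left, which
// makes the alignment deterministic for a given input order.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List nw_affine_path(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  // state 0 = diagonal (match), 1 = up (gap in columns of S), 2 = left
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);

  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) {
      M(i, j) = NEG_INF; X(i, j) = NEG_INF; Y(i, j) = NEG_INF;
    }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) {
    X(i, 0) = gap_open + (i - 1) * gap_extend;
    tX(i, 0) = 1;
  }
  tX(1, 0) = 0;
  for (int j = 1; j <= m; ++j) {
    Y(0, j) = gap_open + (j - 1) * gap_extend;
    tY(0, j) = 2;
  }
  tY(0, 1) = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // diagonal: priority M > X > Y on ties
      double best = M(i - 1, j - 1); int who = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); who = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); who = 2; }
      M(i, j) = best + S(i - 1, j - 1); tM(i, j) = who;

      // up: consume row i
      best = M(i - 1, j) + gap_open; who = 0;
      if (X(i - 1, j) + gap_extend > best) { best = X(i - 1, j) + gap_extend; who = 1; }
      if (Y(i - 1, j) + gap_open > best) { best = Y(i - 1, j) + gap_open; who = 2; }
      X(i, j) = best; tX(i, j) = who;

      // left: consume column j
      best = M(i, j - 1) + gap_open; who = 0;
      if (X(i, j - 1) + gap_open > best) { best = X(i, j - 1) + gap_open; who = 1; }
      if (Y(i, j - 1) + gap_extend > best) { best = Y(i, j - 1) + gap_extend; who = 2; }
      Y(i, j) = best; tY(i, j) = who;
    }
  }

  double score = M(n, m); int state = 0;
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  std::vector<int> p1, p2;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM(i, j);
      p1.push_back(i); p2.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tX(i, j);
      p1.push_back(i); p2.push_back(0);
      --i; state = prev;
    } else {
      int prev = tY(i, j);
      p1.push_back(0); p2.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(p1.begin(), p1.end());
  std::reverse(p2.begin(), p2.end());

  return List::create(_["path1"] = wrap(p1), _["path2"] = wrap(p2),
                      _["score"] = score);
}
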