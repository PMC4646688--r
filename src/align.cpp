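// Needleman-Wunsch global alignment with affine gaps and deterministic
// traceback (diagonal > up > left; up consumes the query).  Gap of length L
// costs open + (L-1) * extend.
#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// state codes: 0 = M (diagonal), 1 = U (gap in reference, consumes query),
// 2 = L (gap in query, consumes reference)

// [[Rcpp::export(name = ".nw_affine")]]
List nw_affine(IntegerVector q, IntegerVector r, NumericMatrix score,
               double gap_open, double gap_extend) {
  const int n = q.size(), m = r.size();
  // DP matrices, (n+1) x (m+1)
  NumericMatrix M(n + 1, m + 1), U(n + 1, m + 1), L(n + 1, m + 1);
  IntegerMatrix bM(n + 1, m + 1), bU(n + 1, m + 1), bL(n + 1, m + 1);

  M(0, 0) = 0.0; U(0, 0) = NEG_INF; L(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; L(i, 0) = NEG_INF;
    U(i, 0) = gap_open + (i - 1) * gap_extend;
    bU(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; U(0, j) = NEG_INF;
    L(0, j) = gap_open + (j - 1) * gap_extend;
    bL(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = score(q[i - 1], r[j - 1]);
      // M: predecessor preference M > U > L on ties
      double best = M(i - 1, j - 1); int arg = 0;
      if (U(i - 1, j - 1) > best) { best = U(i - 1, j - 1); arg = 1; }
      if (L(i - 1, j - 1) > best) { best = L(i - 1, j - 1); arg = 2; }
      M(i, j) = best + s; bM(i, j) = arg;
      // U: open from M or L, extend from U
      double uo = M(i - 1, j) + gap_open;
      double uu = U(i - 1, j) + gap_extend;
      double ul = L(i - 1, j) + gap_open;
      best = uo; arg = 0;
      if (uu > best) { best = uu; arg = 1; }
      if (ul > best) { best = ul; arg = 2; }
      U(i, j) = best; bU(i, j) = arg;
      // L
      double lo = M(i, j - 1) + gap_open;
      double lu = U(i, j - 1) + gap_open;
      double ll = L(i, j - 1) + gap_extend;
      best = lo; arg = 0;
      if (lu > best) { best = lu; arg = 1; }
      if (ll > best) { best = ll; arg = 2; }
      L(i, j) = best; bL(i, j) = arg;
    }
  }

  // final state preference M > U > L on ties
  double sc = M(n, m); int state = 0;
  if (U(n, m) > sc) { sc = U(n, m); state = 1; }
  if (L(n, m) > sc) { sc = L(n, m); state = 2; }

  // traceback
  std::vector<int> ops; // 0 diag, 1 up, 2 left (reversed order)
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back(0);
      state = bM(i, j); --i; --j;
    } else if (state == 1) {
      ops.push_back(1);
      state = bU(i, j); --i;
    } else {
      ops.push_back(2);
      state = bL(i, j); --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = sc,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
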