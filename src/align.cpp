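#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Gotoh global alignment with affine gaps.
//
// States: M = residues paired (diagonal), X = gap in b / residue of a
// consumed ("up"), Y = gap in a / residue of b consumed ("left").
// A gap of length k costs open + (k - 1) * extend.
// Traceback ties are broken deterministically: M, then X, then Y — both
// when choosing the final state and when choosing each predecessor.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a_idx, IntegerVector b_idx,
                  NumericMatrix sub, double gap_open, double gap_extend) {
  const int n = a_idx.size();
  const int m = b_idx.size();
  const int w = m + 1;

  std::vector<double> M((n + 1) * w, NEG_INF);
  std::vector<double> X((n + 1) * w, NEG_INF);
  std::vector<double> Y((n + 1) * w, NEG_INF);
  // predecessor state per cell/state: 0 = M, 1 = X, 2 = Y, -1 = none
  std::vector<signed char> pM((n + 1) * w, -1);
  std::vector<signed char> pX((n + 1) * w, -1);
  std::vector<signed char> pY((n + 1) * w, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * w] = -gap_open - (i - 1) * gap_extend;
    pX[i * w] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -gap_open - (j - 1) * gap_extend;
    pY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * w + j, d = (i - 1) * w + (j - 1);
      const int u = (i - 1) * w + j, l = i * w + (j - 1);

      // M: pair a[i] with b[j]
      double s = sub(a_idx[i - 1], b_idx[j - 1]);
      double best = M[d]; signed char arg = 0;
      if (X[d] > best) { best = X[d]; arg = 1; }
      if (Y[d] > best) { best = Y[d]; arg = 2; }
      M[c] = (best == NEG_INF) ? NEG_INF : best + s;
      pM[c] = arg;

      // X: consume a[i], gap in b
      best = M[u] - gap_open; arg = 0;
      if (X[u] - gap_extend > best) { best = X[u] - gap_extend; arg = 1; }
      if (Y[u] - gap_open > best) { best = Y[u] - gap_open; arg = 2; }
      X[c] = best; pX[c] = arg;

      // Y: consume b[j], gap in a
      best = M[l] - gap_open; arg = 0;
      if (X[l] - gap_open > best) { best = X[l] - gap_open; arg = 1; }
      if (Y[l] - gap_extend > best) { best = Y[l] - gap_extend; arg = 2; }
      Y[c] = best; pY[c] = arg;
    }
  }

  const int end = n * w + m;
  double score = M[end]; signed char state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::vector<int> a_pos, b_pos;  // 0 marks a gap
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * w + j;
    signed char prev;
    if (state == 0) {
      prev = pM[c];
      a_pos.push_back(i); b_pos.push_back(j);
      --i; --j;
    } else if (state == 1) {
      prev = pX[c];
      a_pos.push_back(i); b_pos.push_back(0);
      --i;
    } else {
      prev = pY[c];
      a_pos.push_back(0); b_pos.push_back(j);
      --j;
    }
    state = prev;
  }
  std::reverse(a_pos.begin(), a_pos.end());
  std::reverse(b_pos.begin(), b_pos.end());

  return List::create(_["score"] = score,
                      _["a_pos"] = wrap(a_pos),
                      _["b_pos"] = wrap(b_pos));
}
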