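#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gotoh local alignment, single best HSP. Sequences arrive as 1-based integer
// codes into the package alphabet; `S` is the full substitution matrix in the
// same coding. A gap of length k costs gap_open + k * gap_ext.
// Traceback state codes: 0 = stop (local start), 1 = from M, 2 = from X
// (gap in subject / consume query), 3 = from Y (gap in query).
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const double open1 = gap_open + gap_ext;
  const double NEG = -1e30;

  std::vector<double> M((n + 1) * (m + 1), 0.0), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  // ptrM: which predecessor fed the match cell (0 start, 1 M, 2 X, 3 Y)
  std::vector<signed char> pM((n + 1) * (m + 1), 0), pX((n + 1) * (m + 1), 0),
      pY((n + 1) * (m + 1), 0);

  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double sub = S(a[i - 1] - 1, b[j - 1] - 1);
      // match cell
      double v = 0.0;
      signed char p = 0;
      const int d = idx(i - 1, j - 1);
      if (M[d] > v) { v = M[d]; p = 1; }
      if (X[d] > v) { v = X[d]; p = 2; }
      if (Y[d] > v) { v = Y[d]; p = 3; }
      const int c = idx(i, j);
      M[c] = v + sub;
      pM[c] = p;
      // X: consume a[i], gap in b
      const int u = idx(i - 1, j);
      double xo = M[u] - open1, xe = X[u] - gap_ext, yo = Y[u] - open1;
      if (xo >= xe && xo >= yo) { X[c] = xo; pX[c] = 1; }
      else if (xe >= yo)        { X[c] = xe; pX[c] = 2; }
      else                      { X[c] = yo; pX[c] = 3; }
      // Y: consume b[j], gap in a (pointer codes are state ids: 3 = Y)
      const int l = idx(i, j - 1);
      double mo = M[l] - open1, ye = Y[l] - gap_ext, xg = X[l] - open1;
      if (mo >= ye && mo >= xg) { Y[c] = mo; pY[c] = 1; }
      else if (ye >= xg)        { Y[c] = ye; pY[c] = 3; }
      else                      { Y[c] = xg; pY[c] = 2; }
      if (M[c] > best) { best = M[c]; bi = i; bj = j; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["n_ident"] = 0,
                        _["aln_len"] = 0);
  }

  // traceback from (bi, bj) in state M
  int i = bi, j = bj, state = 1;
  int n_ident = 0, aln_len = 0;
  int qs = bi, ss = bj;
  while (true) {
    const int c = idx(i, j);
    if (state == 1) {
      ++aln_len;
      if (a[i - 1] == b[j - 1]) ++n_ident;
      qs = i; ss = j;
      const signed char p = pM[c];
      --i; --j;
      if (p == 0) break;
      state = p;
    } else if (state == 2) {
      ++aln_len;
      const signed char p = pX[c];
      --i;
      state = p;
    } else {
      ++aln_len;
      const signed char p = pY[c];
      --j;
      state = p;
    }
  }

  return List::create(_["score"] = best, _["q_start"] = qs, _["q_end"] = bi,
                      _["s_start"] = ss, _["s_end"] = bj,
                      _["n_ident"] = n_ident, _["aln_len"] = aln_len);
}
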