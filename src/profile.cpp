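#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Local Viterbi alignment of a sequence to a profile model.
// mlods: L x A match-state emission log2-odds (vs background); insert states
// emit at background (0 bits). Transition scores arrive already in bits.
// Entry: begin -> M_j at any sequence position, cost `entry_bits`
// (uniform over model positions); exit from any match state is free, and
// flanking sequence residues are emitted by the null model at 0 bits.
// [[Rcpp::export]]
List viterbi_profile_cpp(NumericMatrix mlods, NumericVector tMM,
                         NumericVector tMI, NumericVector tMD,
                         NumericVector tIM, NumericVector tII,
                         NumericVector tDM, NumericVector tDD,
                         IntegerVector seq, double entry_bits) {
  const int L = mlods.nrow(), n = seq.size();
  const double NEG = -1e30;
  // column-major DP over (j in 1..L, i in 1..n); pointers for traceback.
  // pointer codes: 0 begin, 1 M, 2 I, 3 D (predecessor state type)
  std::vector<double> VM(L * (n + 1), NEG), VI(L * (n + 1), NEG),
      VD(L * (n + 1), NEG);
  std::vector<signed char> pMv(L * (n + 1), 0), pIv(L * (n + 1), 0),
      pDv(L * (n + 1), 0);
  auto id = [L](int j, int i) { return i * L + (j - 1); };

  double best = NEG;
  int bj = 0, bi = 0;
  for (int i = 1; i <= n; ++i) {
    const int a = seq[i - 1] - 1;
    for (int j = 1; j <= L; ++j) {
      // M_j emits seq[i]
      double v = entry_bits;  // begin -> M_j
      signed char p = 0;
      if (j > 1) {
        const int d = id(j - 1, i - 1);
        const double fm = VM[d] + tMM[j - 2];
        const double fi = VI[d] + tIM[j - 2];
        const double fd = VD[d] + tDM[j - 2];
        if (fm > v) { v = fm; p = 1; }
        if (fi > v) { v = fi; p = 2; }
        if (fd > v) { v = fd; p = 3; }
      }
      const int c = id(j, i);
      VM[c] = v + mlods(j - 1, a);
      pMv[c] = p;
      if (VM[c] > best) { best = VM[c]; bj = j; bi = i; }
      // I_j emits seq[i] at background (no insert state after M_L)
      if (j < L) {
        const int u = id(j, i - 1);
        const double fm = VM[u] + tMI[j - 1];
        const double fi = VI[u] + tII[j - 1];
        if (fm >= fi) { VI[c] = fm; pIv[c] = 1; }
        else          { VI[c] = fi; pIv[c] = 2; }
      }
      // D_j emits nothing
      if (j > 1) {
        const int l = id(j - 1, i);
        const double fm = VM[l] + tMD[j - 2];
        const double fd = VD[l] + tDD[j - 2];
        if (fm >= fd) { VD[c] = fm; pDv[c] = 1; }
        else          { VD[c] = fd; pDv[c] = 3; }
      }
    }
  }

  if (best <= NEG / 2) {
    return List::create(_["bits"] = R_NegInf, _["model_start"] = NA_INTEGER,
                        _["model_end"] = NA_INTEGER, _["seq_start"] = NA_INTEGER,
                        _["seq_end"] = NA_INTEGER);
  }

  // traceback to the entry point
  int j = bj, i = bi, state = 1;
  int mstart = bj, sstart = bi;
  while (true) {
    const int c = id(j, i);
    if (state == 1) {
      mstart = j; sstart = i;
      const signed char p = pMv[c];
      if (p == 0) break;
      --j; --i; state = p;
    } else if (state == 2) {
      const signed char p = pIv[c];
      --i; state = p;
    } else {
      const signed char p = pDv[c];
      --j; state = p;
    }
  }

  return List::create(_["bits"] = best, _["model_start"] = mstart,
                      _["model_end"] = bj, _["seq_start"] = sstart,
                      _["seq_end"] = bi);
}

// Global profile-profile alignment (Gotoh affine) used by the progressive
// MSA. fa, fb: A x La / A x Lb residue-frequency columns (gap mass excluded).
// Column score = fa' S fb. Returns per-output-column consumption flags.
// [[Rcpp::export]]
List nw_profile_cpp(NumericMatrix fa, NumericMatrix fb, NumericMatrix S,
                    double gap_open, double gap_ext) {
  const int A = fa.nrow();
  const int La = fa.ncol(), Lb = fb.ncol();
  const double open1 = gap_open + gap_ext;
  const double NEG = -1e30;

  // precompute column scores
  NumericMatrix cs(La, Lb);
  // Sfb = S %*% fb  (A x Lb), then cs = t(fa) %*% Sfb
  std::vector<double> Sfb(A * Lb);
  for (int j = 0; j < Lb; ++j)
    for (int x = 0; x < A; ++x) {
      double acc = 0;
      for (int y = 0; y < A; ++y) acc += S(x, y) * fb(y, j);
      Sfb[j * A + x] = acc;
    }
  for (int i = 0; i < La; ++i)
    for (int j = 0; j < Lb; ++j) {
      double acc = 0;
      for (int x = 0; x < A; ++x) acc += fa(x, i) * Sfb[j * A + x];
      cs(i, j) = acc;
    }

  std::vector<double> M((La + 1) * (Lb + 1), NEG), X((La + 1) * (Lb + 1), NEG),
      Y((La + 1) * (Lb + 1), NEG);
  std::vector<signed char> pM((La + 1) * (Lb + 1), 0),
      pX((La + 1) * (Lb + 1), 0), pY((La + 1) * (Lb + 1), 0);
  auto idx = [Lb](int i, int j) { return i * (Lb + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= La; ++i) {
    X[idx(i, 0)] = -open1 - (i - 1) * gap_ext;
    pX[idx(i, 0)] = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= Lb; ++j) {
    Y[idx(0, j)] = -open1 - (j - 1) * gap_ext;
    pY[idx(0, j)] = (j == 1) ? 1 : 3;
  }

  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      const int d = idx(i - 1, j - 1), u = idx(i - 1, j), l = idx(i, j - 1),
                c = idx(i, j);
      double v = M[d];
      signed char p = 1;
      if (X[d] > v) { v = X[d]; p = 2; }
      if (Y[d] > v) { v = Y[d]; p = 3; }
      M[c] = v + cs(i - 1, j - 1);
      pM[c] = p;
      double xo = M[u] - open1, xe = X[u] - gap_ext, yo = Y[u] - open1;
      if (xo >= xe && xo >= yo) { X[c] = xo; pX[c] = 1; }
      else if (xe >= yo)        { X[c] = xe; pX[c] = 2; }
      else                      { X[c] = yo; pX[c] = 3; }
      double mo = M[l] - open1, ye = Y[l] - gap_ext, xg = X[l] - open1;
      if (mo >= ye && mo >= xg) { Y[c] = mo; pY[c] = 1; }
      else if (ye >= xg)        { Y[c] = ye; pY[c] = 3; }
      else                      { Y[c] = xg; pY[c] = 2; }
    }
  }

  const int e = idx(La, Lb);
  int state = 1;
  double bestEnd = M[e];
  if (X[e] > bestEnd) { bestEnd = X[e]; state = 2; }
  if (Y[e] > bestEnd) { bestEnd = Y[e]; state = 3; }

  std::vector<int> useA, useB;  // reversed
  int i = La, j = Lb;
  while (i > 0 || j > 0) {
    const int c = idx(i, j);
    if (state == 1) {
      useA.push_back(1); useB.push_back(1);
      state = pM[c];
      --i; --j;
    } else if (state == 2) {
      useA.push_back(1); useB.push_back(0);
      state = pX[c];
      --i;
    } else {
      useA.push_back(0); useB.push_back(1);
      state = pY[c];
      --j;
    }
  }
  const int K = useA.size();
  LogicalVector ua(K), ub(K);
  for (int k = 0; k < K; ++k) {
    ua[k] = useA[K - 1 - k] == 1;
    ub[k] = useB[K - 1 - k] == 1;
  }
  return List::create(_["score"] = bestEnd, _["use_a"] = ua, _["use_b"] = ub);
}
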