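#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap alignment over a precomputed column-score matrix S (n1 x n2).
// Works for residue-vs-residue (S from a substitution matrix) and for
// profile-vs-profile (S = t(P1) %*% B %*% P2) alignment alike.
//
// Gap convention: a gap of length k costs open + (k-1) * ext.
// mode: 0 = global (Needleman-Wunsch/Gotoh), 1 = local (Smith-Waterman).
// Returns score and, unless score_only, aligned column index pairs
// (1-based; 0 marks a gap in that dimension).
// [[Rcpp::export]]
List affine_align_cpp(NumericMatrix S, double open, double ext,
                      int mode, bool score_only) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  const bool local = (mode == 1);
  // Layered DP: M ends in a match column, X ends with a gap in dim2
  // (consumes i), Y ends with a gap in dim1 (consumes j).
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // Trace codes: predecessor layer 0/1/2; 3 in TM = local fresh start.
  IntegerMatrix TM(n + 1, m + 1), TX(n + 1, m + 1), TY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = local ? 0.0 : NEG;
    X(i, 0) = local ? NEG : -open - (i - 1) * ext;
    Y(i, 0) = NEG;
    TX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = local ? 0.0 : NEG;
    Y(0, j) = local ? NEG : -open - (j - 1) * ext;
    X(0, j) = NEG;
    TY(0, j) = 2;
  }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d0 = M(i - 1, j - 1), d1 = X(i - 1, j - 1), d2 = Y(i - 1, j - 1);
      double dm = d0; int tm = 0;
      if (d1 > dm) { dm = d1; tm = 1; }
      if (d2 > dm) { dm = d2; tm = 2; }
      if (local && dm < 0.0) { dm = 0.0; tm = 3; } // start a new local segment
      M(i, j) = dm + S(i - 1, j - 1); TM(i, j) = tm;

      double xo = M(i - 1, j) - open, xe = X(i - 1, j) - ext,
             xy = Y(i - 1, j) - open;
      double xv = xo; int tx = 0;
      if (xe > xv) { xv = xe; tx = 1; }
      if (xy > xv) { xv = xy; tx = 2; }
      X(i, j) = xv; TX(i, j) = tx;

      double yo = M(i, j - 1) - open, ye = Y(i, j - 1) - ext,
             yx = X(i, j - 1) - open;
      double yv = yo; int ty = 0;
      if (ye > yv) { yv = ye; ty = 2; }
      if (yx > yv) { yv = yx; ty = 1; }
      Y(i, j) = yv; TY(i, j) = ty;

      if (local && M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  double score; int ci, cj, layer;
  if (local) {
    score = best; ci = bi; cj = bj; layer = 0;
  } else {
    score = M(n, m); layer = 0;
    if (X(n, m) > score) { score = X(n, m); layer = 1; }
    if (Y(n, m) > score) { score = Y(n, m); layer = 2; }
    ci = n; cj = m;
  }
  if (score_only)
    return List::create(_["score"] = score);

  std::vector<int> pa, pb;
  while (ci > 0 || cj > 0) {
    if (layer == 0) {
      if (ci == 0 || cj == 0) break; // local start reached boundary row/col
      int t = TM(ci, cj);
      pa.push_back(ci); pb.push_back(cj);
      --ci; --cj;
      if (local && t == 3) break; // local alignment started at this cell
      layer = t;
    } else if (layer == 1) {
      pa.push_back(ci); pb.push_back(0);
      layer = (TX(ci, cj) == 0) ? 0 : (TX(ci, cj) == 1 ? 1 : 2);
      --ci;
    } else {
      pa.push_back(0); pb.push_back(cj);
      layer = (TY(ci, cj) == 0) ? 0 : (TY(ci, cj) == 2 ? 2 : 1);
      --cj;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["a"] = wrap(pa), _["b"] = wrap(pb));
}
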