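#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman local alignment on integer-coded sequences
// (1-based codes into the substitution matrix). Scores floor at zero;
// traceback starts from the maximum cell, ties broken by smallest row then
// smallest column (the first maximum encountered in row-major order).
// Gap penalties are positive costs: a gap of length L costs
// gap_open + (L - 1) * gap_extend.
//
// Returns list(score, a_aln, b_aln): integer-coded alignments with 0 as gap.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
              double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix tbH(n + 1, m + 1); // 0 stop, 1 diag, 2 from E, 3 from F
  IntegerMatrix tbE(n + 1, m + 1); // 1 opened from H, 0 extended from E
  IntegerMatrix tbF(n + 1, m + 1); // 1 opened from H, 0 extended from F
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e_open = H(i, j - 1) - gap_open;
      double e_ext = E(i, j - 1) - gap_extend;
      if (e_open >= e_ext) { E(i, j) = e_open; tbE(i, j) = 1; }
      else { E(i, j) = e_ext; tbE(i, j) = 0; }
      double f_open = H(i - 1, j) - gap_open;
      double f_ext = F(i - 1, j) - gap_extend;
      if (f_open >= f_ext) { F(i, j) = f_open; tbF(i, j) = 1; }
      else { F(i, j) = f_ext; tbF(i, j) = 0; }
      double diag = H(i - 1, j - 1) + sub(a[i - 1] - 1, b[j - 1] - 1);
      double h = 0.0; int st = 0;
      if (diag > h) { h = diag; st = 1; }
      if (E(i, j) > h) { h = E(i, j); st = 2; }
      if (F(i, j) > h) { h = F(i, j); st = 3; }
      H(i, j) = h; tbH(i, j) = st;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> ra, rb;
  int i = bi, j = bj, layer = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    if (layer == 0) {
      int st = tbH(i, j);
      if (st == 0) break;
      if (st == 1) { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j; }
      else if (st == 2) layer = 1;
      else layer = 2;
    } else if (layer == 1) {
      ra.push_back(0); rb.push_back(b[j - 1]);
      layer = tbE(i, j) == 1 ? 0 : 1;
      --j;
    } else {
      ra.push_back(a[i - 1]); rb.push_back(0);
      layer = tbF(i, j) == 1 ? 0 : 2;
      --i;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = best,
                      _["a_aln"] = IntegerVector(ra.begin(), ra.end()),
                      _["b_aln"] = IntegerVector(rb.begin(), rb.end()));
}
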