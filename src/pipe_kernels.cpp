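#include <Rcpp.h>
using namespace Rcpp;

// Count, for every length-w window (fragment) of the encoded query sequence and
// every protein in `prots`, how many windows of that protein score strictly
// above `theta` under the substitution matrix `submat` (1-based residue codes).
//
// Window scores along a fixed alignment diagonal share w-1 terms, so each
// diagonal is swept once with a sliding-sum recurrence: O(|a| * |p|) per
// protein instead of O(|a| * |p| * w).
//
// [[Rcpp::export]]
IntegerMatrix match_count_table_cpp(IntegerVector a_enc, int w, List prots,
                                    IntegerMatrix submat, int theta) {
  const int la = a_enc.size();
  const int na = la - w + 1;
  const int np = prots.size();
  if (na < 1) return IntegerMatrix(0, np);
  IntegerMatrix out(na, np);
  const int* S = INTEGER(submat);
  const int srows = submat.nrow();
  const int* a = INTEGER(a_enc);

  for (int p = 0; p < np; ++p) {
    IntegerVector bv = prots[p];
    const int lb = bv.size();
    const int nbw = lb - w + 1;
    if (nbw < 1) continue;
    const int* b = INTEGER(bv);
    for (int d = -(na - 1); d <= nbw - 1; ++d) {
      const int i0 = d < 0 ? -d : 0;
      const int iend = (na - 1) < (nbw - 1 - d) ? (na - 1) : (nbw - 1 - d);
      if (i0 > iend) continue;
      long s = 0;
      for (int k = 0; k < w; ++k)
        s += S[(a[i0 + k] - 1) + srows * (b[i0 + d + k] - 1)];
      if (s > theta) out(i0, p)++;
      for (int i = i0 + 1; i <= iend; ++i) {
        s += S[(a[i + w - 1] - 1) + srows * (b[i + d + w - 1] - 1)]
           - S[(a[i - 1] - 1) + srows * (b[i + d - 1] - 1)];
        if (s > theta) out(i, p)++;
      }
    }
  }
  return out;
}

// Sum of substitution scores over aligned positions of two equal-length
// encoded fragments.
//
// [[Rcpp::export]]
int window_score_cpp(IntegerVector f1, IntegerVector f2, IntegerMatrix submat) {
  const int n = f1.size();
  const int* S = INTEGER(submat);
  const int srows = submat.nrow();
  long s = 0;
  for (int k = 0; k < n; ++k) s += S[(f1[k] - 1) + srows * (f2[k] - 1)];
  return (int)s;
}
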