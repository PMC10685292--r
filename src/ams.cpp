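#include <Rcpp.h>
using namespace Rcpp;

// One full sequential AMS sweep over the rows listed in `ord` (0-based row
// indices into the CSR arrays), followed by clamping to the nonnegative
// orthant. For each visited row the upper-bound half-space is handled first,
// then the lower bound against the already-updated inner product; with
// step weights <= 1 at most one of the two can fire per visit.
//
// row_ptr, col_idx, vals: CSR of the dose influence matrix (0-based).
// step_wt: per-row effective relaxation lambda * nu_i * weight_scale.
// row_sq: cached squared Euclidean row norms; rows with row_sq <= 0 are
// skipped (they cannot define a half-space).
// [[Rcpp::export(name = ".ams_sweep_csr")]]
NumericVector ams_sweep_csr(NumericVector x,
                            IntegerVector row_ptr,
                            IntegerVector col_idx,
                            NumericVector vals,
                            NumericVector lower,
                            NumericVector upper,
                            NumericVector row_sq,
                            NumericVector step_wt,
                            IntegerVector ord) {
  NumericVector out = clone(x);
  const int nvisit = ord.size();
  for (int t = 0; t < nvisit; ++t) {
    const int i = ord[t];
    const double nrm = row_sq[i];
    if (nrm <= 0.0) continue;
    const int a = row_ptr[i], b = row_ptr[i + 1];
    double dot = 0.0;
    for (int p = a; p < b; ++p) dot += vals[p] * out[col_idx[p]];
    const double w = step_wt[i];
    const double u = upper[i], l = lower[i];
    if (R_finite(u) && dot > u) {
      const double c = w * (dot - u) / nrm;
      for (int p = a; p < b; ++p) out[col_idx[p]] -= c * vals[p];
      dot -= w * (dot - u);
    }
    if (dot < l) {
      const double c = w * (l - dot) / nrm;
      for (int p = a; p < b; ++p) out[col_idx[p]] += c * vals[p];
    }
  }
  for (int j = 0; j < out.size(); ++j) if (out[j] < 0.0) out[j] = 0.0;
  return out;
}
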