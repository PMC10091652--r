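#include <Rcpp.h>
using namespace Rcpp;

// Batch GSVA enrichment walk over all samples and sets.
// ord:  p x n, 1-based gene indices ordered by decreasing kcdf value.
// rtau: p x n, symmetric rank statistic already raised to tau (rows = genes).
// memb: p x S logical membership matrix.
// Returns S x n scores.
// [[Rcpp::export]]
NumericMatrix cpp_gsva_walk(const IntegerMatrix& ord,
                            const NumericMatrix& rtau,
                            const LogicalMatrix& memb,
                            bool mx_diff) {
  const int p = ord.nrow(), n = ord.ncol(), S = memb.ncol();
  NumericMatrix out(S, n);
  std::vector<int> set_size(S, 0);
  for (int s = 0; s < S; ++s)
    for (int g = 0; g < p; ++g) if (memb(g, s)) ++set_size[s];
  for (int j = 0; j < n; ++j) {
    for (int s = 0; s < S; ++s) {
      const int m = set_size[s];
      double wtot = 0.0;
      for (int g = 0; g < p; ++g) if (memb(g, s)) wtot += rtau(g, j);
      const double out_step = 1.0 / double(p - m);
      double cum_in = 0.0, cum_out = 0.0;
      double max_pos = 0.0, min_neg = 0.0, extreme = 0.0;
      for (int l = 0; l < p; ++l) {
        const int g = ord(l, j) - 1;
        if (memb(g, s)) {
          if (wtot > 0) cum_in += rtau(g, j) / wtot;
          else          cum_in += 1.0 / double(m);  // degenerate all-zero weights
        } else {
          cum_out += out_step;
        }
        const double nu = cum_in - cum_out;
        if (nu > max_pos) max_pos = nu;
        if (nu < min_neg) min_neg = nu;
        if (std::fabs(nu) > std::fabs(extreme)) extreme = nu;
      }
      out(s, j) = mx_diff ? (max_pos + min_neg) : extreme;
    }
  }
  return out;
}
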