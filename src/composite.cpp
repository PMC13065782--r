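// Grouped geometric-medoid selection: for each pixel-year group, pick the
// unmasked observation minimizing the summed squared deviation from the
// per-band medians. Ties go to the earliest observation in time order.

#include <Rcpp.h>
using namespace Rcpp;

static double med(std::vector<double>& v) {
  size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// V: n x B matrix (medoid feature bands), rows sorted by (group, time);
// group: consecutive integer group ids starting at 1; masked: skip row.
// Returns per group the chosen 1-based row index, or 0 when empty.
// [[Rcpp::export(name = ".medoid_groups_cpp")]]
IntegerVector medoid_groups_cpp(NumericMatrix V, IntegerVector group,
                                LogicalVector masked, int nGroups) {
  const int n = V.nrow(), B = V.ncol();
  IntegerVector out(nGroups, 0);
  int i = 0;
  while (i < n) {
    int g = group[i];
    int j = i;
    std::vector<int> rows;
    while (j < n && group[j] == g) {
      if (!masked[j]) rows.push_back(j);
      ++j;
    }
    if (!rows.empty()) {
      std::vector<double> m(B);
      std::vector<double> tmp;
      for (int b = 0; b < B; ++b) {
        tmp.clear();
        for (int r : rows) tmp.push_back(V(r, b));
        m[b] = med(tmp);
      }
      double best = R_PosInf;
      int bestRow = rows[0];
      for (int r : rows) {
        double d = 0.0;
        for (int b = 0; b < B; ++b) {
          double dv = V(r, b) - m[b];
          d += dv * dv;
        }
        if (d < best) { best = d; bestRow = r; } // strict <: earliest wins ties
      }
      out[g - 1] = bestRow + 1;
    }
    i = j;
  }
  return out;
}
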