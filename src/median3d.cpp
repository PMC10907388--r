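#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

static inline int refl(int i, int n) {
  if (i < 0) return -i;
  if (i >= n) return 2 * n - 2 - i;
  return i;
}

// 3x3x3 median filter over a rows x cols x frames array, reflect padding.
// [[Rcpp::export(name = ".median3d")]]
NumericVector median3d(NumericVector arr, IntegerVector dims) {
  const int nr = dims[0], nc = dims[1], nf = dims[2];
  NumericVector out(arr.size());
  std::vector<double> buf(27);
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        int k = 0;
        for (int df = -1; df <= 1; ++df)
          for (int dc = -1; dc <= 1; ++dc)
            for (int dr = -1; dr <= 1; ++dr) {
              const int rr = refl(r + dr, nr);
              const int cc = refl(c + dc, nc);
              const int ff = refl(f + df, nf);
              buf[k++] = arr[rr + (R_xlen_t)nr * (cc + (R_xlen_t)nc * ff)];
            }
        std::nth_element(buf.begin(), buf.begin() + 13, buf.end());
        out[r + (R_xlen_t)nr * (c + (R_xlen_t)nc * f)] = buf[13];
      }
  return out;
}
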