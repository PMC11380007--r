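#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// reflect an index into [0, n-1] (mirror without repeating the edge pixel,
// i.e. index -1 maps to 1, n maps to n-2); matches the R-side padding rule
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i = i % period;
  if (i < 0) i += period;
  if (i >= n) i = period - i;
  return i;
}

// Non-local means on a single channel. Each output pixel is the
// weight-normalised average of window pixels, weights
// exp(-||patch_i - patch_j||^2 / (2 h^2)).
// [[Rcpp::export(name = ".nlm_denoise_cpp")]]
NumericMatrix nlm_denoise_cpp(NumericMatrix img, int patch_size,
                              int window_size, double h) {
  int nr = img.nrow(), nc = img.ncol();
  int pr = patch_size / 2;   // patch radius
  int wr = window_size / 2;  // window radius
  double inv2h2 = 1.0 / (2.0 * h * h);
  NumericMatrix out(nr, nc);

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double wsum = 0.0, vsum = 0.0;
      for (int dr = -wr; dr <= wr; ++dr) {
        for (int dc = -wr; dc <= wr; ++dc) {
          int rj = r + dr, cj = c + dc;
          // squared patch distance between patches at (r,c) and (rj,cj)
          double d2 = 0.0;
          for (int pr_i = -pr; pr_i <= pr; ++pr_i) {
            for (int pc_i = -pr; pc_i <= pr; ++pc_i) {
              double a = img(reflect_index(r + pr_i, nr),
                             reflect_index(c + pc_i, nc));
              double b = img(reflect_index(rj + pr_i, nr),
                             reflect_index(cj + pc_i, nc));
              double diff = a - b;
              d2 += diff * diff;
            }
          }
          double w = std::exp(-d2 * inv2h2);
          wsum += w;
          vsum += w * img(reflect_index(rj, nr), reflect_index(cj, nc));
        }
      }
      out(r, c) = vsum / wsum;
    }
  }
  return out;
}
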