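#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Edge-repeating reflection (OpenCV BORDER_REFLECT): -1 -> 0, n -> n-1.
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Weighted neighborhood sum with reflect padding; kernel is (2r+1)x(2r+1).
// [[Rcpp::export]]
NumericMatrix cpp_correlate2d(const NumericMatrix& img, const NumericMatrix& kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = kernel.nrow(), kc = kernel.ncol();
  const int ri = kr / 2, rj = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = 0; t < kc; ++t) {
        const int jj = reflect_idx(j + t - rj, nc);
        for (int s = 0; s < kr; ++s) {
          const int ii = reflect_idx(i + s - ri, nr);
          acc += kernel(s, t) * img(ii, jj);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(const NumericMatrix& img, int ksize) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = ksize / 2, win = ksize * ksize;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(win);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int m = 0;
      for (int t = -r; t <= r; ++t) {
        const int jj = reflect_idx(j + t, nc);
        for (int s = -r; s <= r; ++s) {
          buf[m++] = img(reflect_idx(i + s, nr), jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + win / 2, buf.end());
      out(i, j) = buf[win / 2];  // win is odd: the middle order statistic
    }
  }
  return out;
}

// Product-of-Gaussians bilateral filter: spatial sigma_d, range sigma_r.
// [[Rcpp::export]]
NumericMatrix cpp_bilateral_filter(const NumericMatrix& img, int ksize,
                                   double sigma_r, double sigma_d) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = ksize / 2;
  const double inv2sd2 = 1.0 / (2.0 * sigma_d * sigma_d);
  const double inv2sr2 = 1.0 / (2.0 * sigma_r * sigma_r);
  NumericMatrix out(nr, nc);
  // spatial weights depend only on the offset
  std::vector<double> wsp((2 * r + 1) * (2 * r + 1));
  for (int t = -r; t <= r; ++t)
    for (int s = -r; s <= r; ++s)
      wsp[(t + r) * (2 * r + 1) + (s + r)] = std::exp(-(double)(s * s + t * t) * inv2sd2);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double center = img(i, j);
      double num = 0.0, den = 0.0;
      for (int t = -r; t <= r; ++t) {
        const int jj = reflect_idx(j + t, nc);
        for (int s = -r; s <= r; ++s) {
          const double v = img(reflect_idx(i + s, nr), jj);
          const double d = v - center;
          const double w = wsp[(t + r) * (2 * r + 1) + (s + r)] * std::exp(-d * d * inv2sr2);
          num += w * v;
          den += w;
        }
      }
      out(i, j) = num / den;
    }
  }
  return out;
}
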