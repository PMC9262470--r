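#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Symmetric (reflect-including-edge) boundary index: ...1 0 | 0 1 ... n-1 | n-1 n-2...
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    else i = 2 * n - i - 1;
  }
  return i;
}

// Magnitude of complex 2-D spatial correlation with reflect padding.
// Output has the input's dimensions; kernel must have odd sides.
// The image is padded once so the accumulation loops are branch-free.
// [[Rcpp::export(name = ".correlate2dMagnitude")]]
NumericMatrix correlate2d_magnitude(NumericMatrix img, NumericMatrix kre,
                                    NumericMatrix kim) {
  const int H = img.nrow(), W = img.ncol();
  const int kh = kre.nrow(), kw = kre.ncol();
  if (kim.nrow() != kh || kim.ncol() != kw)
    stop("real and imaginary kernel parts must have identical dimensions");
  if (kh % 2 == 0 || kw % 2 == 0)
    stop("kernel sides must be odd");
  if (kh > H || kw > W)
    stop("kernel larger than image");
  const int rh = kh / 2, rw = kw / 2;
  const int Hp = H + kh - 1, Wp = W + kw - 1;

  std::vector<double> pad((size_t)Hp * Wp);
  for (int c = 0; c < Wp; ++c) {
    const int cc = reflect_idx(c - rw, W);
    const double *src = &img(0, cc);
    double *dst = &pad[(size_t)c * Hp];
    for (int r = 0; r < Hp; ++r)
      dst[r] = src[reflect_idx(r - rh, H)];
  }

  NumericMatrix out(H, W);
  std::vector<double> accRe(H), accIm(H);
  for (int c = 0; c < W; ++c) {
    std::fill(accRe.begin(), accRe.end(), 0.0);
    std::fill(accIm.begin(), accIm.end(), 0.0);
    for (int kc = 0; kc < kw; ++kc) {
      const double *col = &pad[(size_t)(c + kc) * Hp];
      const double *kreC = &kre(0, kc);
      const double *kimC = &kim(0, kc);
      for (int kr = 0; kr < kh; ++kr) {
        const double wre = kreC[kr], wim = kimC[kr];
        const double *p = col + kr;
        for (int r = 0; r < H; ++r) {
          accRe[r] += p[r] * wre;
          accIm[r] += p[r] * wim;
        }
      }
    }
    double *o = &out(0, c);
    for (int r = 0; r < H; ++r)
      o[r] = std::sqrt(accRe[r] * accRe[r] + accIm[r] * accIm[r]);
  }
  return out;
}
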