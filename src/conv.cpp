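// Gather/scatter kernels for same-padded 1-D convolution over batches
// stored as (n * width) x channels matrices with rows grouped by sample.
// Taps never cross sample boundaries; out-of-range taps contribute zero.
// Copies are contiguous per (tap, channel, sample) for speed.
#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericMatrix& X, int width, int kernel) {
  const int nW = X.nrow(), cin = X.ncol(), half = (kernel - 1) / 2;
  const int nsamp = nW / width;
  NumericMatrix out(nW, kernel * cin);
  const double* xp = X.begin();
  double* op = out.begin();
  for (int j = 0; j < kernel; ++j) {
    const int d = j - half;
    const int p0 = std::max(0, -d);            // first valid position
    const int p1 = std::min(width, width - d); // one past last valid
    if (p1 <= p0) continue;
    for (int c = 0; c < cin; ++c) {
      const double* src = xp + (size_t)c * nW;
      double* dst = op + (size_t)(j * cin + c) * nW;
      for (int s = 0; s < nsamp; ++s) {
        const int r0 = s * width;
        std::copy(src + r0 + p0 + d, src + r0 + p1 + d, dst + r0 + p0);
      }
    }
  }
  return out;
}

// adjoint of im2col: accumulate column-block gradients back onto positions
// [[Rcpp::export]]
NumericMatrix col2im_cpp(const NumericMatrix& dXcol, int width, int kernel,
                         int cin) {
  const int nW = dXcol.nrow(), half = (kernel - 1) / 2;
  const int nsamp = nW / width;
  NumericMatrix out(nW, cin);
  const double* gp = dXcol.begin();
  double* op = out.begin();
  for (int j = 0; j < kernel; ++j) {
    const int d = j - half;
    const int p0 = std::max(0, -d);
    const int p1 = std::min(width, width - d);
    if (p1 <= p0) continue;
    for (int c = 0; c < cin; ++c) {
      const double* src = gp + (size_t)(j * cin + c) * nW;
      double* dst = op + (size_t)c * nW;
      for (int s = 0; s < nsamp; ++s) {
        const int r0 = s * width;
        const double* sp = src + r0 + p0;
        double* dp = dst + r0 + p0 + d;
        for (int p = p0; p < p1; ++p) *dp++ += *sp++;
      }
    }
  }
  return out;
}
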