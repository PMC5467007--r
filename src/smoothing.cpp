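#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Symmetric (half-sample) boundary reflection: indices ...,-2,-1 map to 1,0
// and n,n+1 map to n-1,n-2. Looping handles kernels wider than the axis.
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Separable convolution of a 4D array (x, y, z, t) along the three spatial
// axes. `kernels` holds one normalized, odd-length kernel per spatial axis;
// a length-1 kernel skips that axis. Applied identically to every volume t.
// [[Rcpp::export]]
NumericVector smooth_separable4d(NumericVector x, IntegerVector dim,
                                 List kernels) {
  if (dim.size() != 4) stop("expected a 4D array");
  const R_xlen_t total = (R_xlen_t)dim[0] * dim[1] * dim[2] * dim[3];
  if (x.size() != total) stop("array length does not match dim");

  std::vector<double> a(x.begin(), x.end());
  std::vector<double> b(total);

  for (int ax = 0; ax < 3; ++ax) {
    NumericVector w = kernels[ax];
    const int klen = w.size();
    if (klen <= 1) continue;
    if (klen % 2 == 0) stop("kernel length must be odd");
    const int r = (klen - 1) / 2;
    const int n = dim[ax];

    R_xlen_t stride = 1;
    for (int d = 0; d < ax; ++d) stride *= dim[d];
    const R_xlen_t blocksz = stride * n;
    const R_xlen_t nblocks = total / blocksz;

    for (R_xlen_t blk = 0; blk < nblocks; ++blk) {
      const R_xlen_t base = blk * blocksz;
      for (R_xlen_t inner = 0; inner < stride; ++inner) {
        const R_xlen_t off = base + inner;
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j) {
            const int src = reflect(i + j, n);
            acc += w[j + r] * a[off + (R_xlen_t)src * stride];
          }
          b[off + (R_xlen_t)i * stride] = acc;
        }
      }
    }
    a.swap(b);
  }

  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}
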