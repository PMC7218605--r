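#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Hot inner kernels of the convolutional trunk. The grid batch is laid out
// as a C x (L*W*n) matrix: position index runs row-fastest within a sample,
// samples are concatenated. Convolutions use implicit zero padding at the
// grid border, which is numerically identical to real padding cells because
// the pad embedding is the zero vector and convolutions carry no bias.

// column-major offset decomposition shared by the kernels
static inline int src_col(int r, int c, int s, int L, int W) {
  return r + (c * L) + (s * L * W);
}

// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_im2col(const NumericMatrix& A, int L, int W, int n,
                         int kh, int kw) {
  const int C = A.nrow();
  const int total = L * W * n;
  const int khw = kh * kw;
  NumericMatrix out(C * khw, total);
  const double* a = &A(0, 0);
  double* o = &out(0, 0);
  const int orows = C * khw;
  const int dr0 = -(kh - 1) / 2, dc0 = -(kw - 1) / 2;
  for (int k = 0; k < khw; ++k) {
    const int dr = dr0 + (k % kh);
    const int dc = dc0 + (k / kh);
    const int rowoff = k * C;
    for (int s = 0; s < n; ++s) {
      for (int c = 0; c < W; ++c) {
        const int c2 = c + dc;
        if (c2 < 0 || c2 >= W) continue;
        for (int r = 0; r < L; ++r) {
          const int r2 = r + dr;
          if (r2 < 0 || r2 >= L) continue;
          const int t = src_col(r, c, s, L, W);
          const int u = src_col(r2, c2, s, L, W);
          std::memcpy(o + (size_t)t * orows + rowoff, a + (size_t)u * C,
                      C * sizeof(double));
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_col2im(const NumericMatrix& dXcol, int C, int L, int W,
                         int n, int kh, int kw) {
  const int total = L * W * n;
  const int khw = kh * kw;
  NumericMatrix out(C, total);
  const double* d = &dXcol(0, 0);
  double* o = &out(0, 0);
  const int drows = dXcol.nrow();
  const int dr0 = -(kh - 1) / 2, dc0 = -(kw - 1) / 2;
  for (int k = 0; k < khw; ++k) {
    const int dr = dr0 + (k % kh);
    const int dc = dc0 + (k / kh);
    const int rowoff = k * C;
    for (int s = 0; s < n; ++s) {
      for (int c = 0; c < W; ++c) {
        const int c2 = c + dc;
        if (c2 < 0 || c2 >= W) continue;
        for (int r = 0; r < L; ++r) {
          const int r2 = r + dr;
          if (r2 < 0 || r2 >= L) continue;
          const int t = src_col(r, c, s, L, W);
          const int u = src_col(r2, c2, s, L, W);
          const double* from = d + (size_t)t * drows + rowoff;
          double* to = o + (size_t)u * C;
          for (int i = 0; i < C; ++i) to[i] += from[i];
        }
      }
    }
  }
  return out;
}

// global max over the P positions of each sample; the running maximum is
// initialized at 0, the exact contribution of any cropped all-padding
// region (ReLU activations are nonnegative); arg = 0 marks that baseline
// [[Rcpp::export(rng = false)]]
List cpp_maxpool(const NumericMatrix& A, int P, int n) {
  const int C = A.nrow();
  NumericMatrix pooled(C, n);
  IntegerMatrix arg(C, n);
  const double* a = &A(0, 0);
  for (int s = 0; s < n; ++s) {
    double* ps = &pooled(0, s);
    int* as = &arg(0, s);
    for (int p = 0; p < P; ++p) {
      const double* col = a + ((size_t)s * P + p) * C;
      for (int i = 0; i < C; ++i) {
        if (col[i] > ps[i]) { ps[i] = col[i]; as[i] = p + 1; }
      }
    }
  }
  return List::create(_["pooled"] = pooled, _["arg"] = arg);
}

// [[Rcpp::export(rng = false)]]
NumericMatrix cpp_maxpool_grad(const NumericMatrix& dpooled,
                               const IntegerMatrix& arg, int P) {
  const int C = dpooled.nrow();
  const int n = dpooled.ncol();
  NumericMatrix out(C, (size_t)P * n);
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < C; ++i) {
      const int p = arg(i, s);
      if (p > 0) out(i, (size_t)s * P + (p - 1)) = dpooled(i, s);
    }
  }
  return out;
}
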