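// Memory-layout kernels for the convolutional classifier.
//
// Batches live in two layouts:
//  * "array"  : (H, W, C, B) column-major numeric vector;
//  * "matrix" : rows = (spatial position, image) with position fastest,
//               columns = channels.
// im2col unrolls valid k x k patches so convolution becomes one GEMM
// (done in R via %*% / BLAS); col2im is its adjoint (scatter-add).

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int B, int k) {
  const int outH = H - k + 1, outW = W - k + 1;
  const int npos = outH * outW, ksz = k * k * C;
  NumericMatrix out((R_xlen_t)npos * B, ksz);
  const double *xp = REAL(x);
  double *op = REAL(out);
  for (int ch = 0; ch < C; ++ch)
    for (int dc = 0; dc < k; ++dc)
      for (int dr = 0; dr < k; ++dr) {
        const int col = dr + k * dc + k * k * ch;
        double *ocol = op + (R_xlen_t)col * npos * B;
        for (int b = 0; b < B; ++b) {
          const double *xim = xp + (R_xlen_t)b * H * W * C + (R_xlen_t)ch * H * W;
          double *od = ocol + (R_xlen_t)b * npos;
          for (int c2 = 0; c2 < outW; ++c2)
            std::memcpy(od + (R_xlen_t)c2 * outH,
                        xim + (R_xlen_t)(c2 + dc) * H + dr,
                        sizeof(double) * outH);
        }
      }
  return out;
}

// adjoint of im2col: accumulate patch columns back into the input array
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int B, int k) {
  const int outH = H - k + 1, outW = W - k + 1;
  const int npos = outH * outW;
  NumericVector x((R_xlen_t)H * W * C * B);
  double *xp = REAL(x);
  const double *cp = REAL(cols);
  for (int ch = 0; ch < C; ++ch)
    for (int dc = 0; dc < k; ++dc)
      for (int dr = 0; dr < k; ++dr) {
        const int col = dr + k * dc + k * k * ch;
        const double *ccol = cp + (R_xlen_t)col * npos * B;
        for (int b = 0; b < B; ++b) {
          double *xim = xp + (R_xlen_t)b * H * W * C + (R_xlen_t)ch * H * W;
          const double *src = ccol + (R_xlen_t)b * npos;
          for (int c2 = 0; c2 < outW; ++c2) {
            double *dst = xim + (R_xlen_t)(c2 + dc) * H + dr;
            const double *s = src + (R_xlen_t)c2 * outH;
            for (int r = 0; r < outH; ++r) dst[r] += s[r];
          }
        }
      }
  return x;
}

// 2x2 stride-2 max pooling on the matrix layout; argmax is the 1-based row
// index into the input matrix (unique per output element, so the backward
// pass is a plain scatter)
// [[Rcpp::export]]
List maxpool_cpp(NumericMatrix a, int convH, int convW, int B) {
  const int npos = convH * convW;
  const int ph = convH / 2, pw = convW / 2, nout = ph * pw;
  const int nch = a.ncol();
  NumericMatrix out((R_xlen_t)nout * B, nch);
  IntegerMatrix arg((R_xlen_t)nout * B, nch);
  const double *ap = REAL(a);
  double *op = REAL(out);
  int *gp = INTEGER(arg);
  for (int ch = 0; ch < nch; ++ch) {
    const double *acol = ap + (R_xlen_t)ch * a.nrow();
    double *ocol = op + (R_xlen_t)ch * out.nrow();
    int *gcol = gp + (R_xlen_t)ch * arg.nrow();
    for (int b = 0; b < B; ++b) {
      const double *ai = acol + (R_xlen_t)b * npos;
      double *oi = ocol + (R_xlen_t)b * nout;
      int *gi = gcol + (R_xlen_t)b * nout;
      for (int c2 = 0; c2 < pw; ++c2)
        for (int r = 0; r < ph; ++r) {
          const int base = (2 * c2) * convH + 2 * r;
          const int cand[4] = {base, base + 1, base + convH, base + convH + 1};
          double best = ai[cand[0]];
          int bi = cand[0];
          for (int t = 1; t < 4; ++t)
            if (ai[cand[t]] > best) { best = ai[cand[t]]; bi = cand[t]; }
          oi[r + c2 * ph] = best;
          gi[r + c2 * ph] = bi + b * npos + 1;
        }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// matrix layout -> array layout
// [[Rcpp::export]]
NumericVector mat_to_arr_cpp(NumericMatrix m, int H, int W, int B) {
  const int npos = H * W, C = m.ncol();
  NumericVector x((R_xlen_t)npos * C * B);
  double *xp = REAL(x);
  const double *mp = REAL(m);
  for (int ch = 0; ch < C; ++ch) {
    const double *mc = mp + (R_xlen_t)ch * m.nrow();
    for (int b = 0; b < B; ++b)
      std::memcpy(xp + (R_xlen_t)b * npos * C + (R_xlen_t)ch * npos,
                  mc + (R_xlen_t)b * npos, sizeof(double) * npos);
  }
  return x;
}

// array layout -> matrix layout
// [[Rcpp::export]]
NumericMatrix arr_to_mat_cpp(NumericVector x, int H, int W, int C, int B) {
  const int npos = H * W;
  NumericMatrix m((R_xlen_t)npos * B, C);
  const double *xp = REAL(x);
  double *mp = REAL(m);
  for (int ch = 0; ch < C; ++ch) {
    double *mc = mp + (R_xlen_t)ch * m.nrow();
    for (int b = 0; b < B; ++b)
      std::memcpy(mc + (R_xlen_t)b * npos,
                  xp + (R_xlen_t)b * npos * C + (R_xlen_t)ch * npos,
                  sizeof(double) * npos);
  }
  return m;
}

// in-place bias add + ReLU on a freshly allocated GEMM result
// [[Rcpp::export]]
void relu_bias_inplace_cpp(NumericMatrix a, NumericVector b) {
  const int n = a.nrow(), m = a.ncol();
  for (int j = 0; j < m; ++j) {
    const double bj = b[j];
    double *col = REAL(a) + (R_xlen_t)j * n;
    for (int i = 0; i < n; ++i) {
      const double v = col[i] + bj;
      col[i] = v > 0 ? v : 0;
    }
  }
}

// max-pool backward fused with the ReLU mask: route each pooled gradient
// to its argmax position when the pooled activation was positive
// [[Rcpp::export]]
NumericMatrix maxpool_bwd_cpp(NumericMatrix dP, IntegerMatrix arg,
                              NumericMatrix P, int nrows) {
  const int m = dP.ncol(), n = dP.nrow();
  NumericMatrix dA(nrows, m);
  for (int j = 0; j < m; ++j) {
    const double *dp = REAL(dP) + (R_xlen_t)j * n;
    const double *pp = REAL(P) + (R_xlen_t)j * n;
    const int *ag = INTEGER(arg) + (R_xlen_t)j * n;
    double *da = REAL(dA) + (R_xlen_t)j * nrows;
    for (int i = 0; i < n; ++i)
      if (pp[i] > 0) da[ag[i] - 1] = dp[i];
  }
  return dA;
}

// The training loop allocates and frees several >50 MB buffers per
// minibatch; with glibc's default mmap threshold every one round-trips
// through mmap/munmap and page faulting. Raising the threshold lets the
// heap reuse those buffers.
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::export]]
void tune_allocator_cpp() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}
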