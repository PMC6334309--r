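// Data-movement kernels for the built-in CNN training engine.
// Activation tensors use dim = c(H, W, N, C), column-major, so that the
// channel dimension is outermost: a [H*W*N, C] matrix view of the same
// memory gives per-channel columns (convenient for batch-norm), and the
// im2col product cols %*% W reshapes straight back to c(oh, ow, N, F)
// without a permutation.

#include <Rcpp.h>
using namespace Rcpp;

// Unfold x [H,W,N,C] into a matrix [oh*ow*N, k*k*C] where column
// ki + kj*k + c*k*k holds the (ki,kj) kernel tap of channel c for every
// output position. Out-of-range taps (zero padding) read as 0.
// [[Rcpp::export]]
NumericMatrix ng_im2col(NumericVector x, int H, int W, int N, int C,
                        int k, int stride, int pad, int oh, int ow) {
  NumericMatrix out(oh * (R_xlen_t)ow * N, k * (R_xlen_t)k * C);
  const double* px = x.begin();
  double* po = out.begin();
  const R_xlen_t ncolrows = (R_xlen_t)oh * ow * N;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        R_xlen_t col = ki + (R_xlen_t)kj * k + (R_xlen_t)c * k * k;
        double* pcol = po + col * ncolrows;
        for (int n = 0; n < N; ++n) {
          const double* pxc = px + ((R_xlen_t)c * N + n) * H * W;
          for (int j = 0; j < ow; ++j) {
            int xj = j * stride + kj - pad;
            bool jin = (xj >= 0 && xj < W);
            double* pd = pcol + (R_xlen_t)n * oh * ow + (R_xlen_t)j * oh;
            if (!jin) {
              for (int i = 0; i < oh; ++i) pd[i] = 0.0;
            } else {
              const double* ps = pxc + (R_xlen_t)xj * H;
              for (int i = 0; i < oh; ++i) {
                int xi = i * stride + ki - pad;
                pd[i] = (xi >= 0 && xi < H) ? ps[xi] : 0.0;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of ng_im2col: fold a [oh*ow*N, k*k*C] matrix back into an
// accumulated [H,W,N,C] tensor.
// [[Rcpp::export]]
NumericVector ng_col2im(NumericMatrix cols, int H, int W, int N, int C,
                        int k, int stride, int pad, int oh, int ow) {
  NumericVector x((R_xlen_t)H * W * N * C);
  double* px = x.begin();
  const double* po = cols.begin();
  const R_xlen_t ncolrows = (R_xlen_t)oh * ow * N;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        R_xlen_t col = ki + (R_xlen_t)kj * k + (R_xlen_t)c * k * k;
        const double* pcol = po + col * ncolrows;
        for (int n = 0; n < N; ++n) {
          double* pxc = px + ((R_xlen_t)c * N + n) * H * W;
          for (int j = 0; j < ow; ++j) {
            int xj = j * stride + kj - pad;
            if (xj < 0 || xj >= W) continue;
            const double* ps = pcol + (R_xlen_t)n * oh * ow + (R_xlen_t)j * oh;
            double* pd = pxc + (R_xlen_t)xj * H;
            for (int i = 0; i < oh; ++i) {
              int xi = i * stride + ki - pad;
              if (xi >= 0 && xi < H) pd[xi] += ps[i];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, N, C);
  return x;
}

// Max pooling on [H,W,N,C] with a k x k window and given stride, no padding.
// Returns the pooled tensor and the 1-based linear argmax index into x for
// the backward scatter.
// [[Rcpp::export]]
List ng_maxpool(NumericVector x, int H, int W, int N, int C,
                int k, int stride) {
  int oh = (H - k) / stride + 1;
  int ow = (W - k) / stride + 1;
  R_xlen_t olen = (R_xlen_t)oh * ow * N * C;
  NumericVector out(olen);
  IntegerVector arg(olen);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const R_xlen_t xoff = ((R_xlen_t)c * N + n) * H * W;
      const R_xlen_t ooff = ((R_xlen_t)c * N + n) * oh * ow;
      for (int j = 0; j < ow; ++j) {
        for (int i = 0; i < oh; ++i) {
          double best = R_NegInf;
          R_xlen_t bestIdx = 0;
          for (int kj = 0; kj < k; ++kj) {
            R_xlen_t coloff = xoff + (R_xlen_t)(j * stride + kj) * H;
            for (int ki = 0; ki < k; ++ki) {
              R_xlen_t idx = coloff + i * stride + ki;
              if (px[idx] > best) { best = px[idx]; bestIdx = idx; }
            }
          }
          R_xlen_t o = ooff + (R_xlen_t)j * oh + i;
          out[o] = best;
          arg[o] = (int)(bestIdx + 1);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, N, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// Scatter pooled gradients back to input positions (accumulating, since
// stride < k windows overlap).
// [[Rcpp::export]]
NumericVector ng_maxpool_backward(NumericVector dout, IntegerVector argmax,
                                  int H, int W, int N, int C) {
  NumericVector dx((R_xlen_t)H * W * N * C);
  double* pdx = dx.begin();
  const double* pd = dout.begin();
  const int* pa = argmax.begin();
  R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) pdx[pa[i] - 1] += pd[i];
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return dx;
}
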