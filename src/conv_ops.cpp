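// Low-level kernels for the CNN layers. Tensors are dense double arrays in
// R's column-major order with layout [H, W, N, C] (linear index
// i + H*(j + W*(n + N*c))). This layout makes batch normalization a
// per-column reduction and lets convolution run as a single GEMM against
// the patch matrix built here.
#include <Rcpp.h>
using namespace Rcpp;

// Patch matrix for a k x k, stride-1, zero-padded ("same") convolution.
// Returns (H*W*N) x (k*k*C); row p = flattened output pixel (i, j, n),
// column r = (ki, kj, c) patch offset. Out-of-canvas taps contribute 0.
// [[Rcpp::export]]
NumericMatrix im2col_hwnc(NumericVector x, int H, int W, int N, int C,
                          int k, int pad) {
  const int P = H * W * N;
  NumericMatrix cols(P, k * k * C);
  const double* px = x.begin();
  double* pc = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * (kj + k * c);
        double* colr = pc + (R_xlen_t)r * P;
        for (int n = 0; n < N; ++n) {
          for (int j = 0; j < W; ++j) {
            const int sj = j + kj - pad;
            double* dst = colr + (R_xlen_t)H * (j + (R_xlen_t)W * n);
            if (sj < 0 || sj >= W) {
              for (int i = 0; i < H; ++i) dst[i] = 0.0;
              continue;
            }
            const double* src =
                px + (R_xlen_t)H * (sj + (R_xlen_t)W * (n + (R_xlen_t)N * c));
            for (int i = 0; i < H; ++i) {
              const int si = i + ki - pad;
              dst[i] = (si < 0 || si >= H) ? 0.0 : src[si];
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col_hwnc: scatter-add patch-matrix gradients back onto the
// input tensor.
// [[Rcpp::export]]
NumericVector col2im_hwnc(NumericMatrix cols, int H, int W, int N, int C,
                          int k, int pad) {
  const int P = H * W * N;
  NumericVector x((R_xlen_t)P * C);
  double* px = x.begin();
  const double* pc = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * (kj + k * c);
        const double* colr = pc + (R_xlen_t)r * P;
        for (int n = 0; n < N; ++n) {
          for (int j = 0; j < W; ++j) {
            const int sj = j + kj - pad;
            if (sj < 0 || sj >= W) continue;
            const double* src = colr + (R_xlen_t)H * (j + (R_xlen_t)W * n);
            double* dst =
                px + (R_xlen_t)H * (sj + (R_xlen_t)W * (n + (R_xlen_t)N * c));
            for (int i = 0; i < H; ++i) {
              const int si = i + ki - pad;
              if (si >= 0 && si < H) dst[si] += src[i];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, N, C);
  return x;
}

// 2x2 stride-2 max pooling. Returns the pooled tensor and the 0-based
// linear argmax index of each output element in the input tensor (ties go
// to the first element scanned, so the result is deterministic). H and W
// must be even.
// [[Rcpp::export]]
List maxpool2x2(NumericVector x, int H, int W, int N, int C) {
  const int Ho = H / 2, Wo = W / 2;
  const R_xlen_t P = (R_xlen_t)Ho * Wo * N * C;
  NumericVector out(P);
  IntegerVector idx(P);
  const double* px = x.begin();
  R_xlen_t p = 0;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const R_xlen_t base = (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          R_xlen_t best = base + 2 * i + (R_xlen_t)H * (2 * j);
          double bv = px[best];
          const R_xlen_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int t = 0; t < 3; ++t) {
            if (px[cand[t]] > bv) { bv = px[cand[t]]; best = cand[t]; }
          }
          out[p] = bv;
          idx[p] = (int)best;
          ++p;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// Route pooled-output gradients back to the argmax positions.
// [[Rcpp::export]]
NumericVector maxpool2x2_backward(NumericVector dy, IntegerVector idx,
                                  int H, int W, int N, int C) {
  NumericVector dx((R_xlen_t)H * W * N * C);
  for (R_xlen_t p = 0; p < dy.size(); ++p) dx[idx[p]] += dy[p];
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return dx;
}

// SegNet-style unpooling: place each value of x at the argmax position its
// paired encoder pool recorded; everything else stays zero.
// [[Rcpp::export]]
NumericVector unpool2x2(NumericVector x, IntegerVector idx,
                        int H, int W, int N, int C) {
  NumericVector out((R_xlen_t)H * W * N * C);
  for (R_xlen_t p = 0; p < x.size(); ++p) out[idx[p]] = x[p];
  out.attr("dim") = IntegerVector::create(H, W, N, C);
  return out;
}

// Gradient of unpool2x2: gather from the scattered positions.
// [[Rcpp::export]]
NumericVector unpool2x2_backward(NumericVector dy, IntegerVector idx,
                                 int Ho, int Wo, int N, int C) {
  NumericVector dx((R_xlen_t)Ho * Wo * N * C);
  for (R_xlen_t p = 0; p < dx.size(); ++p) dx[p] = dy[idx[p]];
  dx.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return dx;
}
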