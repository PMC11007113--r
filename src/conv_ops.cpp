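#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Tensor layout everywhere: dim (C, H, W, N), channels fastest (column-major).
// im2col unrolls kh x kw patches so convolution becomes one BLAS matmul:
//   rows ordered (c fastest, then dh, then dw); columns ordered (ho, wo, n).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W, int N,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(C * kh * kw, (R_xlen_t)Ho * Wo * N);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t crows = (R_xlen_t)C * kh * kw;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t col = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        double* oc = op + col * crows;
        const int h0 = ho * stride - pad, w0 = wo * stride - pad;
        for (int dw = 0; dw < kw; ++dw) {
          const int w = w0 + dw;
          for (int dh = 0; dh < kh; ++dh) {
            const int h = h0 + dh;
            double* dst = oc + ((R_xlen_t)dw * kh + dh) * C;
            if (h >= 0 && h < H && w >= 0 && w < W) {
              const double* src =
                  xp + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
              std::memcpy(dst, src, C * sizeof(double));
            } else {
              std::memset(dst, 0, C * sizeof(double));
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add column gradients back onto the input tensor.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W, int N,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector x((R_xlen_t)C * H * W * N);
  double* xp = x.begin();
  const double* cp = cols.begin();
  const R_xlen_t crows = (R_xlen_t)C * kh * kw;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t col = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        const double* oc = cp + col * crows;
        const int h0 = ho * stride - pad, w0 = wo * stride - pad;
        for (int dw = 0; dw < kw; ++dw) {
          const int w = w0 + dw;
          if (w < 0 || w >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int h = h0 + dh;
            if (h < 0 || h >= H) continue;
            const double* src = oc + ((R_xlen_t)dw * kh + dh) * C;
            double* dst =
                xp + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(C, H, W, N);
  return x;
}

// Max pooling over (ph, pw) windows with the given stride (no padding).
// Returns the pooled tensor plus 1-based argmax positions for the backward pass.
// [[Rcpp::export]]
List maxpool_cpp(NumericVector x, int C, int H, int W, int N,
                 int ph, int pw, int stride) {
  const int Ho = (H - ph) / stride + 1;
  const int Wo = (W - pw) / stride + 1;
  NumericVector y((R_xlen_t)C * Ho * Wo * N);
  IntegerVector arg((R_xlen_t)C * Ho * Wo * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          R_xlen_t besti = 0;
          for (int dw = 0; dw < pw; ++dw) {
            const int w = wo * stride + dw;
            for (int dh = 0; dh < ph; ++dh) {
              const int h = ho * stride + dh;
              const R_xlen_t idx =
                  c + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
              if (xp[idx] > best) { best = xp[idx]; besti = idx; }
            }
          }
          const R_xlen_t oidx =
              c + (R_xlen_t)C * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
          yp[oidx] = best;
          ap[oidx] = (int)(besti + 1);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}
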