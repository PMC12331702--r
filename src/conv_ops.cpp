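#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Image batches travel through the network channel-first: C x H x W x B
// arrays (column-major, C fastest). With this layout a convolution's
// matmul output (Cout x OH*OW*B) is already in array order, so no
// permutations are needed anywhere in the forward/backward pass.

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Unroll k x k windows: result is (C*k*k) x (OH*OW*B), rows ordered
// (c fastest, then kh, then kw), columns ordered (oh, ow, b).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int C, int H, int W, int B,
                         int k, int stride, int pad) {
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  NumericMatrix out(C * k * k, OH * OW * B);
  const double *xp = x.begin();
  double *op = out.begin();
  const size_t CH = (size_t)C * H, CHW = (size_t)C * H * W;
  const int Ckk = C * k * k;
  for (int b = 0; b < B; ++b) {
    const double *img = xp + CHW * b;
    for (int ow = 0; ow < OW; ++ow) {
      const int w0 = ow * stride - pad;
      for (int oh = 0; oh < OH; ++oh) {
        const int h0 = oh * stride - pad;
        double *col = op + (size_t)Ckk * (oh + (size_t)OH * (ow + (size_t)OW * b));
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            double *dst = col + C * (kh + k * kw);
            if (h < 0 || h >= H || w < 0 || w >= W) {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            } else {
              const double *src = img + C * h + CH * w;
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add column gradients back to images.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int C, int H, int W, int B,
                         int k, int stride, int pad) {
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  NumericVector x((size_t)C * H * W * B);
  double *xp = x.begin();
  const double *cp = cols.begin();
  const size_t CH = (size_t)C * H, CHW = (size_t)C * H * W;
  const int Ckk = C * k * k;
  for (int b = 0; b < B; ++b) {
    double *img = xp + CHW * b;
    for (int ow = 0; ow < OW; ++ow) {
      const int w0 = ow * stride - pad;
      for (int oh = 0; oh < OH; ++oh) {
        const int h0 = oh * stride - pad;
        const double *col = cp + (size_t)Ckk * (oh + (size_t)OH * (ow + (size_t)OW * b));
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            if (h < 0 || h >= H) continue;
            const double *src = col + C * (kh + k * kw);
            double *dst = img + C * h + CH * w;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return x;
}

// Max pooling on (C,H,W,B); returns pooled values (C,OH,OW,B) and
// 1-based argmax linear indices into the input for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int C, int H, int W, int B,
                 int k, int stride, int pad) {
  const int OH = out_size(H, k, stride, pad);
  const int OW = out_size(W, k, stride, pad);
  NumericVector out((size_t)C * OH * OW * B);
  IntegerVector arg((size_t)C * OH * OW * B);
  const double *xp = x.begin();
  const size_t CH = (size_t)C * H, CHW = (size_t)C * H * W;
  for (int b = 0; b < B; ++b) {
    const double *img = xp + CHW * b;
    const size_t base = CHW * b;
    for (int ow = 0; ow < OW; ++ow) {
      const int w0 = ow * stride - pad;
      for (int oh = 0; oh < OH; ++oh) {
        const int h0 = oh * stride - pad;
        const size_t oi0 = (size_t)C * (oh + (size_t)OH * (ow + (size_t)OW * b));
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              if (h < 0 || h >= H) continue;
              const size_t idx = (size_t)c + C * h + CH * w;
              const double v = img[idx];
              if (v > best) { best = v; besti = idx; }
            }
          }
          out[oi0 + c] = best;
          arg[oi0 + c] = (int)(base + besti) + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}
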