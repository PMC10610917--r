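// Low-level numeric kernels for the conv-net engine: im2col/col2im,
// max-pooling with argmax, bilinear resizing with its adjoint, and the
// largest-empty-rectangle search used when cropping calibration targets.
// Feature maps are numeric arrays with dim (H, W, C, N), column-major.
#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static inline int conv_out_dim(int n, int k, int pad, int stride, int dil) {
  int eff = dil * (k - 1) + 1;
  return (n + 2 * pad - eff) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad, int dil) {
  int Ho = conv_out_dim(H, kh, pad, stride, dil);
  int Wo = conv_out_dim(W, kw, pad, stride, dil);
  if (Ho < 1 || Wo < 1) stop("im2col: output size is empty");
  NumericMatrix col(kh * kw * C, Ho * Wo * N);
  const double* xp = x.begin();
  double* cp = col.begin();
  int nrow = kh * kw * C;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        int colix = oh + Ho * ow + Ho * Wo * n;
        double* dst = cp + (R_xlen_t)colix * nrow;
        for (int c = 0; c < C; ++c) {
          const double* src = xp + (R_xlen_t)(c + C * n) * H * W;
          for (int kc = 0; kc < kw; ++kc) {
            int w = ow * stride - pad + dil * kc;
            for (int kr = 0; kr < kh; ++kr) {
              int h = oh * stride - pad + dil * kr;
              double v = 0.0;
              if (h >= 0 && h < H && w >= 0 && w < W)
                v = src[h + (R_xlen_t)H * w];
              dst[kr + kh * kc + kh * kw * c] = v;
            }
          }
        }
      }
    }
  }
  return col;
}

// Adjoint of im2col: scatter columns back into the input gradient.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix col, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad, int dil) {
  int Ho = conv_out_dim(H, kh, pad, stride, dil);
  int Wo = conv_out_dim(W, kw, pad, stride, dil);
  NumericVector out((R_xlen_t)H * W * C * N);
  double* op = out.begin();
  const double* cp = col.begin();
  int nrow = kh * kw * C;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        int colix = oh + Ho * ow + Ho * Wo * n;
        const double* src = cp + (R_xlen_t)colix * nrow;
        for (int c = 0; c < C; ++c) {
          double* dst = op + (R_xlen_t)(c + C * n) * H * W;
          for (int kc = 0; kc < kw; ++kc) {
            int w = ow * stride - pad + dil * kc;
            for (int kr = 0; kr < kh; ++kr) {
              int h = oh * stride - pad + dil * kr;
              if (h >= 0 && h < H && w >= 0 && w < W)
                dst[h + (R_xlen_t)H * w] += src[kr + kh * kc + kh * kw * c];
            }
          }
        }
      }
    }
  }
  return out;
}

// Max pooling; ceil mode lets windows overhang (overhang treated as -Inf).
// Returns the pooled map and 1-based linear argmax indices into x.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int H, int W, int C, int N,
                 int k, int stride, int pad, bool ceil_mode) {
  int extra = ceil_mode ? stride - 1 : 0;
  int Ho = (H + 2 * pad - k + extra) / stride + 1;
  int Wo = (W + 2 * pad - k + extra) / stride + 1;
  // drop windows that start past the (padded) input
  while ((Ho - 1) * stride - pad >= H) --Ho;
  while ((Wo - 1) * stride - pad >= W) --Wo;
  if (Ho < 1 || Wo < 1) stop("maxpool: output size is empty");
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* src = xp + (R_xlen_t)(c + C * n) * H * W;
      R_xlen_t base_in = (R_xlen_t)(c + C * n) * H * W;
      R_xlen_t base_out = (R_xlen_t)(c + C * n) * Ho * Wo;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double best = -DBL_MAX;
          R_xlen_t besti = -1;
          for (int kc = 0; kc < k; ++kc) {
            int w = ow * stride - pad + kc;
            if (w < 0 || w >= W) continue;
            for (int kr = 0; kr < k; ++kr) {
              int h = oh * stride - pad + kr;
              if (h < 0 || h >= H) continue;
              double v = src[h + (R_xlen_t)H * w];
              if (v > best) { best = v; besti = h + (R_xlen_t)H * w; }
            }
          }
          out[base_out + oh + (R_xlen_t)Ho * ow] = best;
          idx[base_out + oh + (R_xlen_t)Ho * ow] = (int)(base_in + besti + 1);
        }
      }
    }
  }
  out.attr("outdim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["value"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector g, IntegerVector idx, R_xlen_t n_in) {
  NumericVector out(n_in);
  for (R_xlen_t i = 0; i < g.size(); ++i) out[idx[i] - 1] += g[i];
  return out;
}

struct BilinWeights {
  std::vector<int> i0, i1;
  std::vector<double> w0, w1;
};

static BilinWeights bilin_axis(int n_in, int n_out) {
  // align_corners = FALSE convention (pixel centres at half-integers)
  BilinWeights bw;
  bw.i0.resize(n_out); bw.i1.resize(n_out);
  bw.w0.resize(n_out); bw.w1.resize(n_out);
  double scale = (double)n_in / n_out;
  for (int o = 0; o < n_out; ++o) {
    double src = (o + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    int i0 = (int)std::floor(src);
    int i1 = i0 + 1 < n_in ? i0 + 1 : i0;
    double frac = src - i0;
    bw.i0[o] = i0; bw.i1[o] = i1;
    bw.w0[o] = 1.0 - frac; bw.w1[o] = frac;
  }
  return bw;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int H, int W, int C, int N,
                                  int Ho, int Wo) {
  BilinWeights bh = bilin_axis(H, Ho), bw = bilin_axis(W, Wo);
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* src = xp + (R_xlen_t)cn * H * W;
    double* dst = op + (R_xlen_t)cn * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        double v =
          bh.w0[oh] * (bw.w0[ow] * src[bh.i0[oh] + (R_xlen_t)H * bw.i0[ow]] +
                       bw.w1[ow] * src[bh.i0[oh] + (R_xlen_t)H * bw.i1[ow]]) +
          bh.w1[oh] * (bw.w0[ow] * src[bh.i1[oh] + (R_xlen_t)H * bw.i0[ow]] +
                       bw.w1[ow] * src[bh.i1[oh] + (R_xlen_t)H * bw.i1[ow]]);
        dst[oh + (R_xlen_t)Ho * ow] = v;
      }
    }
  }
  return out;
}

// Adjoint of cpp_resize_bilinear (scatter with the same weights).
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector g, int H, int W, int C, int N,
                                      int Ho, int Wo) {
  BilinWeights bh = bilin_axis(H, Ho), bw = bilin_axis(W, Wo);
  NumericVector out((R_xlen_t)H * W * C * N);
  const double* gp = g.begin();
  double* op = out.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* src = gp + (R_xlen_t)cn * Ho * Wo;
    double* dst = op + (R_xlen_t)cn * H * W;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        double v = src[oh + (R_xlen_t)Ho * ow];
        dst[bh.i0[oh] + (R_xlen_t)H * bw.i0[ow]] += bh.w0[oh] * bw.w0[ow] * v;
        dst[bh.i0[oh] + (R_xlen_t)H * bw.i1[ow]] += bh.w0[oh] * bw.w1[ow] * v;
        dst[bh.i1[oh] + (R_xlen_t)H * bw.i0[ow]] += bh.w1[oh] * bw.w0[ow] * v;
        dst[bh.i1[oh] + (R_xlen_t)H * bw.i1[ow]] += bh.w1[oh] * bw.w1[ow] * v;
      }
    }
  }
  return out;
}

// Largest axis-aligned rectangle of FALSE cells in a logical matrix
// (histogram-stack method, O(H*W)). Returns 0-based half-open
// c(row0, row1, col0, col1); all -1 if no free cell exists.
// Ties: larger area first, then smaller row0, then smaller col0.
// [[Rcpp::export]]
IntegerVector cpp_largest_free_rect(LogicalMatrix blocked) {
  int H = blocked.nrow(), W = blocked.ncol();
  std::vector<int> heights(W, 0);
  long best_area = 0;
  int br0 = -1, br1 = -1, bc0 = -1, bc1 = -1;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c)
      heights[c] = blocked(r, c) ? 0 : heights[c] + 1;
    // largest rectangle in histogram `heights`, bottom row = r
    std::vector<int> stack_c, stack_h;
    for (int c = 0; c <= W; ++c) {
      int h = (c == W) ? 0 : heights[c];
      int start = c;
      while (!stack_h.empty() && stack_h.back() > h) {
        int hh = stack_h.back(), cc = stack_c.back();
        stack_h.pop_back(); stack_c.pop_back();
        long area = (long)hh * (c - cc);
        int r0 = r - hh + 1, c0 = cc;
        if (area > best_area ||
            (area == best_area && (r0 < br0 || (r0 == br0 && c0 < bc0)))) {
          best_area = area;
          br0 = r0; br1 = r + 1; bc0 = c0; bc1 = c;
        }
        start = cc;
      }
      if (c < W && (stack_h.empty() || stack_h.back() < h)) {
        stack_c.push_back(start);
        stack_h.push_back(h);
      }
    }
  }
  return IntegerVector::create(br0, br1, bc0, bc1);
}
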