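// Low-level tensor primitives for the 2D+time U-Nets. Activations are
// stored as N x C matrices where voxel n = t + T*(h + H*w) for a block of
// dims (T, H, W); convolution is im2col + BLAS gemm (gemm done in R).
#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col3(const NumericMatrix& X, IntegerVector dims, int k) {
  int T = dims[0], H = dims[1], W = dims[2];
  int N = T * H * W, C = X.ncol(), k3 = k * k * k, r = k / 2;
  NumericMatrix out(N, C * k3);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    for (int dw = -r; dw <= r; ++dw)
      for (int dh = -r; dh <= r; ++dh)
        for (int dt = -r; dt <= r; ++dt) {
          int j = (dt + r) + k * ((dh + r) + k * (dw + r));
          double* oc = &out(0, c * k3 + j);
          for (int w = 0; w < W; ++w) {
            int ww = w + dw;
            if (ww < 0 || ww >= W) continue;
            for (int h = 0; h < H; ++h) {
              int hh = h + dh;
              if (hh < 0 || hh >= H) continue;
              int t0 = std::max(0, -dt), t1 = std::min(T, T - dt);
              if (t1 <= t0) continue;
              std::memcpy(oc + t0 + T * (h + H * w),
                          xc + dt + t0 + T * (hh + H * ww),
                          sizeof(double) * (t1 - t0));
            }
          }
        }
  }
  return out;
}

// adjoint of im2col3: scatter-add patch gradients back to voxels
// [[Rcpp::export]]
NumericMatrix cpp_col2im3(const NumericMatrix& G, IntegerVector dims, int k, int C) {
  int T = dims[0], H = dims[1], W = dims[2];
  int N = T * H * W, k3 = k * k * k, r = k / 2;
  NumericMatrix out(N, C);
  for (int c = 0; c < C; ++c) {
    double* oc = &out(0, c);
    for (int dw = -r; dw <= r; ++dw)
      for (int dh = -r; dh <= r; ++dh)
        for (int dt = -r; dt <= r; ++dt) {
          int j = (dt + r) + k * ((dh + r) + k * (dw + r));
          const double* gc = &G(0, c * k3 + j);
          for (int w = 0; w < W; ++w) {
            int ww = w + dw;
            if (ww < 0 || ww >= W) continue;
            for (int h = 0; h < H; ++h) {
              int hh = h + dh;
              if (hh < 0 || hh >= H) continue;
              int t0 = std::max(0, -dt), t1 = std::min(T, T - dt);
              double* dst = oc + dt + t0 + T * (hh + H * ww);
              const double* src = gc + t0 + T * (h + H * w);
              for (int t = t0; t < t1; ++t) dst[t - t0] += src[t - t0];
            }
          }
        }
  }
  return out;
}

// 2x average pooling in (t, h, w); dims must be even
// [[Rcpp::export]]
NumericMatrix cpp_avgpool3(const NumericMatrix& X, IntegerVector dims) {
  int T = dims[0], H = dims[1], W = dims[2], C = X.ncol();
  int To = T / 2, Ho = H / 2, Wo = W / 2;
  NumericMatrix out(To * Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    double* oc = &out(0, c);
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int t = 0; t < To; ++t) {
          double s = 0.0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              for (int dt = 0; dt < 2; ++dt)
                s += xc[(2 * t + dt) + T * ((2 * h + dh) + H * (2 * w + dw))];
          oc[t + To * (h + Ho * w)] = s / 8.0;
        }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_avgpool3_bwd(const NumericMatrix& dY, IntegerVector dims_in) {
  int T = dims_in[0], H = dims_in[1], W = dims_in[2], C = dY.ncol();
  int To = T / 2, Ho = H / 2, Wo = W / 2;
  NumericMatrix out(T * H * W, C);
  for (int c = 0; c < C; ++c) {
    const double* gc = &dY(0, c);
    double* oc = &out(0, c);
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int t = 0; t < To; ++t) {
          double g = gc[t + To * (h + Ho * w)] / 8.0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              for (int dt = 0; dt < 2; ++dt)
                oc[(2 * t + dt) + T * ((2 * h + dh) + H * (2 * w + dw))] = g;
        }
  }
  return out;
}

// nearest-neighbour 2x upsampling in (t, h, w)
// [[Rcpp::export]]
NumericMatrix cpp_upsample3(const NumericMatrix& X, IntegerVector dims_in) {
  int T = dims_in[0], H = dims_in[1], W = dims_in[2], C = X.ncol();
  int To = T * 2, Ho = H * 2, Wo = W * 2;
  NumericMatrix out(To * Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    double* oc = &out(0, c);
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int t = 0; t < To; ++t)
          oc[t + To * (h + Ho * w)] =
            xc[(t / 2) + T * ((h / 2) + H * (w / 2))];
  }
  return out;
}

// adjoint of nearest upsampling: sum over the 8 children
// [[Rcpp::export]]
NumericMatrix cpp_upsample3_bwd(const NumericMatrix& dY, IntegerVector dims_in) {
  int T = dims_in[0], H = dims_in[1], W = dims_in[2], C = dY.ncol();
  int To = T * 2, Ho = H * 2, Wo = W * 2;
  NumericMatrix out(T * H * W, C);
  for (int c = 0; c < C; ++c) {
    const double* gc = &dY(0, c);
    double* oc = &out(0, c);
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int t = 0; t < To; ++t)
          oc[(t / 2) + T * ((h / 2) + H * (w / 2))] +=
            gc[t + To * (h + Ho * w)];
  }
  return out;
}

// separable 2D correlation with a symmetric 1D kernel, zero padding
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur2(const NumericMatrix& img, NumericVector kern) {
  int H = img.nrow(), W = img.ncol(), K = kern.size(), r = K / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double s = 0.0;
      int j0 = std::max(0, r - y), j1 = std::min(K, H + r - y);
      for (int j = j0; j < j1; ++j) s += kern[j] * img(y + j - r, x);
      tmp(y, x) = s;
    }
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double s = 0.0;
      int j0 = std::max(0, r - x), j1 = std::min(K, W + r - x);
      for (int j = j0; j < j1; ++j) s += kern[j] * tmp(y, x + j - r);
      out(y, x) = s;
    }
  return out;
}

// per-frame separable blur of an H x W x F stack (zero padding)
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(const NumericVector& arr, IntegerVector dims,
                              NumericVector kern) {
  int H = dims[0], W = dims[1], F = dims[2], K = kern.size(), r = K / 2;
  NumericVector out(H * W * F);
  std::vector<double> tmp(H * W);
  for (int f = 0; f < F; ++f) {
    const double* src = &arr[(size_t)f * H * W];
    double* dst = &out[(size_t)f * H * W];
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        double s = 0.0;
        int j0 = std::max(0, r - y), j1 = std::min(K, H + r - y);
        for (int j = j0; j < j1; ++j) s += kern[j] * src[(y + j - r) + H * x];
        tmp[y + H * x] = s;
      }
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        double s = 0.0;
        int j0 = std::max(0, r - x), j1 = std::min(K, W + r - x);
        for (int j = j0; j < j1; ++j) s += kern[j] * tmp[y + H * (x + j - r)];
        dst[y + H * x] = s;
      }
  }
  out.attr("dim") = dims;
  return out;
}
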