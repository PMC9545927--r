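// Kaiser-Bessel spreading / interpolation kernels for gridding NUFFT and
// iterative density-compensation. Grids are oversampled k-space matrices
// (rows = y, cols = x) with DC at index 0 after ifftshift; sample
// coordinates arrive in fine-grid index units and wrap modulo the grid
// size (exact for integer pixel offsets, see nufft.R).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double bessel_i0(double x) {
  // series for small |x|, asymptotic for large; |rel err| < 1e-15 range used
  double ax = std::fabs(x);
  if (ax < 40.0) {
    double t = x * x / 4.0, term = 1.0, sum = 1.0;
    for (int k = 1; k < 200; ++k) {
      term *= t / (double(k) * double(k));
      sum += term;
      if (term < sum * 1e-17) break;
    }
    return sum;
  }
  double inv = 1.0 / ax;
  double p = 1.0 + inv * (0.125 + inv * (0.0703125 + inv * (0.0732421875 +
             inv * 0.112152099609375)));
  return std::exp(ax) * p / std::sqrt(2.0 * M_PI * ax);
}

static inline double kb_val(double d, double halfw, double beta, double i0beta) {
  double t = d / halfw;
  double arg = 1.0 - t * t;
  if (arg <= 0.0) return 0.0;
  return bessel_i0(beta * std::sqrt(arg)) / i0beta;
}

// [[Rcpp::export]]
arma::cx_vec cpp_kb_interp(const arma::cx_mat& K, const arma::vec& gy,
                           const arma::vec& gx, double width, double beta) {
  int ny = K.n_rows, nx = K.n_cols, n = gy.n_elem;
  double halfw = width / 2.0, i0b = bessel_i0(beta);
  arma::cx_vec out(n, arma::fill::zeros);
  for (int j = 0; j < n; ++j) {
    double cy = gy[j], cx = gx[j];
    int y0 = (int)std::ceil(cy - halfw), y1 = (int)std::floor(cy + halfw);
    int x0 = (int)std::ceil(cx - halfw), x1 = (int)std::floor(cx + halfw);
    std::complex<double> acc(0.0, 0.0);
    for (int yy = y0; yy <= y1; ++yy) {
      double wy = kb_val(yy - cy, halfw, beta, i0b);
      if (wy == 0.0) continue;
      int yi = ((yy % ny) + ny) % ny;
      for (int xx = x0; xx <= x1; ++xx) {
        double wx = kb_val(xx - cx, halfw, beta, i0b);
        if (wx == 0.0) continue;
        int xi = ((xx % nx) + nx) % nx;
        acc += K(yi, xi) * (wy * wx);
      }
    }
    out[j] = acc;
  }
  return out;
}

// [[Rcpp::export]]
arma::cx_mat cpp_kb_spread(const arma::cx_vec& vals, const arma::vec& gy,
                           const arma::vec& gx, int ny, int nx,
                           double width, double beta) {
  int n = vals.n_elem;
  double halfw = width / 2.0, i0b = bessel_i0(beta);
  arma::cx_mat K(ny, nx, arma::fill::zeros);
  for (int j = 0; j < n; ++j) {
    double cy = gy[j], cx = gx[j];
    int y0 = (int)std::ceil(cy - halfw), y1 = (int)std::floor(cy + halfw);
    int x0 = (int)std::ceil(cx - halfw), x1 = (int)std::floor(cx + halfw);
    for (int yy = y0; yy <= y1; ++yy) {
      double wy = kb_val(yy - cy, halfw, beta, i0b);
      if (wy == 0.0) continue;
      int yi = ((yy % ny) + ny) % ny;
      for (int xx = x0; xx <= x1; ++xx) {
        double wx = kb_val(xx - cx, halfw, beta, i0b);
        if (wx == 0.0) continue;
        int xi = ((xx % nx) + nx) % nx;
        K(yi, xi) += vals[j] * (wy * wx);
      }
    }
  }
  return K;
}

// sample-domain density operator for Pipe-Menon iterations:
// (C w)_j = sum_i w_i * kb2(g_j - g_i), realized as interp(spread(w))
// [[Rcpp::export]]
arma::vec cpp_kb_density(const arma::vec& w, const arma::vec& gy,
                         const arma::vec& gx, int ny, int nx,
                         double width, double beta) {
  arma::cx_vec wc(w, arma::vec(w.n_elem, arma::fill::zeros));
  arma::cx_mat K = cpp_kb_spread(wc, gy, gx, ny, nx, width, beta);
  arma::cx_vec r = cpp_kb_interp(K, gy, gx, width, beta);
  return arma::real(r);
}

// Fourier transform of the (I0-normalized) KB kernel, for deapodization.
// f in cycles per fine-grid sample.
// [[Rcpp::export]]
NumericVector cpp_kb_ft(NumericVector f, double width, double beta) {
  int n = f.size();
  NumericVector out(n);
  double i0b = bessel_i0(beta);
  for (int j = 0; j < n; ++j) {
    double a = M_PI * width * f[j];
    double d = beta * beta - a * a;
    double v;
    if (d > 0) {
      double s = std::sqrt(d);
      v = (s < 1e-12) ? 1.0 : std::sinh(s) / s;
    } else {
      double s = std::sqrt(-d);
      v = (s < 1e-12) ? 1.0 : std::sin(s) / s;
    }
    out[j] = width * v / i0b;
  }
  return out;
}
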