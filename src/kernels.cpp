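// Low-level numeric kernels for the segmentation networks.
//
// Feature maps are R arrays of dim (H, W, C), column-major, matching
// arma::cube (rows, cols, slices).  Convolution weights are matrices of dim
// (Cout, Cin*k*k) with 0-based column index  c*k*k + ki*k + kj  where c is
// the input channel, ki the kernel row offset and kj the kernel col offset.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad, int dil) {
  int eff = (k - 1) * dil + 1;
  return (n + 2 * pad - eff) / stride + 1;
}

static arma::cube as_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 2)
    return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], 1, false, true);
  return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false, true);
}

static NumericVector cube_to_r(const arma::cube& c) {
  NumericVector out(c.begin(), c.end());
  out.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

// im2col: (Cin*k*k) x (Ho*Wo); output pixel column index = ho + Ho*wo
static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int dil, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(C * k * k, (size_t)Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const size_t j = ho + (size_t)Ho * wo;
      double* cj = col.colptr(j);
      for (int c = 0; c < C; ++c) {
        for (int ki = 0; ki < k; ++ki) {
          int hi = ho * stride - pad + ki * dil;
          if (hi < 0 || hi >= H) continue;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj * dil;
            if (wi < 0 || wi >= W) continue;
            cj[c * k * k + ki * k + kj] = x(hi, wi, c);
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericMatrix w, NumericVector b,
                         int k, int stride, int pad, int dil) {
  arma::cube xc = as_cube(x);
  const int Ho = out_size(xc.n_rows, k, stride, pad, dil);
  const int Wo = out_size(xc.n_cols, k, stride, pad, dil);
  const int Cout = w.nrow();
  if ((int)xc.n_slices * k * k != w.ncol())
    stop("conv2d: weight shape does not match input channels");
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false, true);
  arma::mat col = im2col(xc, k, stride, pad, dil, Ho, Wo);
  arma::mat out = wm * col;  // Cout x (Ho*Wo)
  out.each_col() += arma::vec(b.begin(), Cout);
  arma::cube y(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    y.slice(c) = arma::reshape(out.row(c).t(), Ho, Wo);
  return cube_to_r(y);
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericMatrix w, NumericVector gy,
                         int k, int stride, int pad, int dil) {
  arma::cube xc = as_cube(x);
  arma::cube gc = as_cube(gy);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Ho = gc.n_rows, Wo = gc.n_cols, Cout = gc.n_slices;
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false, true);

  arma::mat gmat(Cout, (size_t)Ho * Wo);
  for (int c = 0; c < Cout; ++c)
    gmat.row(c) = arma::vectorise(gc.slice(c)).t();

  arma::mat col = im2col(xc, k, stride, pad, dil, Ho, Wo);
  arma::mat gw = gmat * col.t();
  arma::vec gb = arma::sum(gmat, 1);

  // col2im scatter-add
  arma::mat gcol = wm.t() * gmat;  // (C*k*k) x (Ho*Wo)
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const size_t j = ho + (size_t)Ho * wo;
      const double* cj = gcol.colptr(j);
      for (int c = 0; c < C; ++c) {
        for (int ki = 0; ki < k; ++ki) {
          int hi = ho * stride - pad + ki * dil;
          if (hi < 0 || hi >= H) continue;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj * dil;
            if (wi < 0 || wi >= W) continue;
            gx(hi, wi, c) += cj[c * k * k + ki * k + kj];
          }
        }
      }
    }
  }
  NumericMatrix gwr(gw.n_rows, gw.n_cols);
  std::copy(gw.begin(), gw.end(), gwr.begin());
  return List::create(_["gx"] = cube_to_r(gx), _["gw"] = gwr,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Bilinear resize (align_corners = TRUE); exact linear map so the backward
// pass is its transpose with identical tap weights.
static inline void src_taps(int i2, int n2, int n, int& i0, int& i1, double& t) {
  if (n2 == 1 || n == 1) { i0 = 0; i1 = 0; t = 0.0; return; }
  double s = (double)i2 * (n - 1) / (n2 - 1);
  i0 = (int)std::floor(s);
  if (i0 >= n - 1) i0 = n - 2;
  i1 = i0 + 1;
  t = s - i0;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int H2, int W2) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  arma::cube y(H2, W2, C);
  for (int j = 0; j < W2; ++j) {
    int j0, j1; double u;
    src_taps(j, W2, W, j0, j1, u);
    for (int i = 0; i < H2; ++i) {
      int i0, i1; double t;
      src_taps(i, H2, H, i0, i1, t);
      for (int c = 0; c < C; ++c) {
        y(i, j, c) = (1 - t) * (1 - u) * xc(i0, j0, c) + t * (1 - u) * xc(i1, j0, c)
                   + (1 - t) * u * xc(i0, j1, c) + t * u * xc(i1, j1, c);
      }
    }
  }
  return cube_to_r(y);
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_backward(NumericVector gy, int H, int W) {
  arma::cube gc = as_cube(gy);
  const int H2 = gc.n_rows, W2 = gc.n_cols, C = gc.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int j = 0; j < W2; ++j) {
    int j0, j1; double u;
    src_taps(j, W2, W, j0, j1, u);
    for (int i = 0; i < H2; ++i) {
      int i0, i1; double t;
      src_taps(i, H2, H, i0, i1, t);
      for (int c = 0; c < C; ++c) {
        double g = gc(i, j, c);
        gx(i0, j0, c) += (1 - t) * (1 - u) * g;
        gx(i1, j0, c) += t * (1 - u) * g;
        gx(i0, j1, c) += (1 - t) * u * g;
        gx(i1, j1, c) += t * u * g;
      }
    }
  }
  return cube_to_r(gx);
}

// Rotation about the image centre, inverse mapping, constant-fill padding.
// method: 0 = bilinear (images), 1 = nearest (label masks).
// [[Rcpp::export]]
NumericMatrix cpp_rotate(NumericMatrix x, double angle_deg, int method,
                         double fill) {
  const int H = x.nrow(), W = x.ncol();
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  NumericMatrix y(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      // inverse rotation of output pixel (i, j) into source coordinates
      double dy = i - cy, dx = j - cx;
      double sy = ct * dy + st * dx + cy;
      double sx = -st * dy + ct * dx + cx;
      if (method == 1) {
        int ri = (int)std::lround(sy), rj = (int)std::lround(sx);
        y(i, j) = (ri >= 0 && ri < H && rj >= 0 && rj < W) ? x(ri, rj) : fill;
      } else {
        int i0 = (int)std::floor(sy), j0 = (int)std::floor(sx);
        double t = sy - i0, u = sx - j0;
        double acc = 0.0;
        for (int di = 0; di <= 1; ++di) {
          for (int dj = 0; dj <= 1; ++dj) {
            int ii = i0 + di, jj = j0 + dj;
            double wgt = (di ? t : 1 - t) * (dj ? u : 1 - u);
            double v = (ii < 0 || ii >= H || jj < 0 || jj >= W) ? fill
                                                                : x(ii, jj);
            acc += wgt * v;
          }
        }
        y(i, j) = acc;
      }
    }
  }
  return y;
}

// 8-connected component labelling of a binary mask (iterative flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.emplace_back(i, j);
      lab(i, j) = next;
      while (!stack.empty()) {
        auto p = stack.back();
        stack.pop_back();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.emplace_back(ii, jj);
            }
          }
        }
      }
    }
  }
  return lab;
}
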