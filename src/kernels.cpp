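// Dense and depthwise 3D convolution kernels (im2col + GEMM) plus
// surface-distance helpers. Feature maps are column-major arrays with
// dims (D, H, W, C); "same" zero padding; odd kernel edge k with dilation r
// pads by r*(k-1)/2 on each side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// voxel-major patch matrix: V x (k^3*C); column r = c*k^3 + offset index,
// so writes along the fastest (d) axis are contiguous
static inline arma::mat im2col3(const double* x, int D, int H, int W, int C,
                                int k, int dil) {
  const int p = dil * (k - 1) / 2;
  const int K3 = k * k * k;
  const long V = (long)D * H * W;
  arma::mat cols(V, K3 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (long)c * V;
    for (int kw = 0; kw < k; ++kw) {
      const int ow = kw * dil - p;
      for (int kh = 0; kh < k; ++kh) {
        const int oh = kh * dil - p;
        for (int kd = 0; kd < k; ++kd) {
          const int od = kd * dil - p;
          const int r = c * K3 + kd + k * kh + k * k * kw;
          double* col = cols.colptr(r);
          for (int w = 0; w < W; ++w) {
            const int sw = w + ow;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + oh;
              if (sh < 0 || sh >= H) continue;
              const int d0 = std::max(0, -od);
              const int d1 = std::min(D, D - od);
              const double* src = xc + d0 + od + (long)D * (sh + (long)H * sw);
              double* dst = col + d0 + (long)D * (h + (long)H * w);
              memcpy(dst, src, (d1 - d0) * sizeof(double));
            }
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add transpose of im2col3 (cols is V x k^3*C)
static void col2im3(const arma::mat& cols, double* dx, int D, int H, int W,
                    int C, int k, int dil) {
  const int p = dil * (k - 1) / 2;
  const int K3 = k * k * k;
  const long V = (long)D * H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (long)c * V;
    for (int kw = 0; kw < k; ++kw) {
      const int ow = kw * dil - p;
      for (int kh = 0; kh < k; ++kh) {
        const int oh = kh * dil - p;
        for (int kd = 0; kd < k; ++kd) {
          const int od = kd * dil - p;
          const int r = c * K3 + kd + k * kh + k * k * kw;
          const double* col = cols.colptr(r);
          for (int w = 0; w < W; ++w) {
            const int sw = w + ow;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + oh;
              if (sh < 0 || sh >= H) continue;
              const int d0 = std::max(0, -od);
              const int d1 = std::min(D, D - od);
              double* dst = xc + d0 + od + (long)D * (sh + (long)H * sw);
              const double* src = col + d0 + (long)D * (h + (long)H * w);
              for (int d = 0; d < d1 - d0; ++d) dst[d] += src[d];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fw(NumericVector x, IntegerVector dims,
                           NumericMatrix Wm, NumericVector b, int k, int dil) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Cout = Wm.nrow();
  if (Wm.ncol() != k * k * k * C) stop("kernel/channel mismatch in conv3");
  const long V = (long)D * H * W;
  arma::mat cols = im2col3(x.begin(), D, H, W, C, k, dil);
  arma::mat Wa(Wm.begin(), Cout, Wm.ncol(), false);
  NumericVector out((long)V * Cout);
  arma::mat Y(out.begin(), V, Cout, false, true);
  Y = cols * Wa.t();                  // V x Cout matches (D,H,W,Cout) layout
  Y.each_row() += arma::rowvec(b.begin(), Cout);
  out.attr("dim") = IntegerVector::create(D, H, W, Cout);
  return out;
}

// single-precision twin of im2col3 (mixed-precision training path)
static inline arma::fmat im2col3f(const double* x, int D, int H, int W,
                                  int C, int k, int dil) {
  const int p = dil * (k - 1) / 2;
  const int K3 = k * k * k;
  const long V = (long)D * H * W;
  arma::fmat cols(V, K3 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (long)c * V;
    for (int kw = 0; kw < k; ++kw) {
      const int ow = kw * dil - p;
      for (int kh = 0; kh < k; ++kh) {
        const int oh = kh * dil - p;
        for (int kd = 0; kd < k; ++kd) {
          const int od = kd * dil - p;
          const int r = c * K3 + kd + k * kh + k * k * kw;
          float* col = cols.colptr(r);
          for (int w = 0; w < W; ++w) {
            const int sw = w + ow;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + oh;
              if (sh < 0 || sh >= H) continue;
              const int d0 = std::max(0, -od);
              const int d1 = std::min(D, D - od);
              const double* src = xc + d0 + od + (long)D * (sh + (long)H * sw);
              float* dst = col + d0 + (long)D * (h + (long)H * w);
              for (int d = 0; d < d1 - d0; ++d) dst[d] = (float)src[d];
            }
          }
        }
      }
    }
  }
  return cols;
}

static void col2im3f(const arma::fmat& cols, double* dx, int D, int H,
                     int W, int C, int k, int dil) {
  const int p = dil * (k - 1) / 2;
  const int K3 = k * k * k;
  const long V = (long)D * H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (long)c * V;
    for (int kw = 0; kw < k; ++kw) {
      const int ow = kw * dil - p;
      for (int kh = 0; kh < k; ++kh) {
        const int oh = kh * dil - p;
        for (int kd = 0; kd < k; ++kd) {
          const int od = kd * dil - p;
          const int r = c * K3 + kd + k * kh + k * k * kw;
          const float* col = cols.colptr(r);
          for (int w = 0; w < W; ++w) {
            const int sw = w + ow;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + oh;
              if (sh < 0 || sh >= H) continue;
              const int d0 = std::max(0, -od);
              const int d1 = std::min(D, D - od);
              double* dst = xc + d0 + od + (long)D * (sh + (long)H * sw);
              const float* src = col + d0 + (long)D * (h + (long)H * w);
              for (int d = 0; d < d1 - d0; ++d) dst[d] += (double)src[d];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_conv3_fwc32(NumericVector x, IntegerVector dims,
                     NumericMatrix Wm, NumericVector b, int k, int dil) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Cout = Wm.nrow();
  if (Wm.ncol() != k * k * k * C) stop("kernel/channel mismatch in conv3");
  const long V = (long)D * H * W;
  arma::fmat* cols = new arma::fmat(im2col3f(x.begin(), D, H, W, C, k, dil));
  arma::mat Wd(Wm.begin(), Cout, Wm.ncol(), false);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wd);
  arma::fmat Y = (*cols) * Wf.t();
  NumericVector out((long)V * Cout);
  double* o = out.begin();
  const float* y = Y.memptr();
  for (int co = 0; co < Cout; ++co) {
    const double bc = b[co];
    for (long v = 0; v < V; ++v) o[co * V + v] = (double)y[co * V + v] + bc;
  }
  out.attr("dim") = IntegerVector::create(D, H, W, Cout);
  XPtr<arma::fmat> ptr(cols, true);
  return List::create(_["y"] = out, _["cols"] = ptr);
}

// [[Rcpp::export]]
List cpp_conv3_bwc32(SEXP colsPtr, IntegerVector dims,
                     NumericMatrix Wm, NumericVector dy, int k, int dil) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Cout = Wm.nrow();
  const long V = (long)D * H * W;
  arma::mat dYd(dy.begin(), V, Cout, false);
  arma::fmat dY = arma::conv_to<arma::fmat>::from(dYd);
  arma::fmat& cols = *XPtr<arma::fmat>(colsPtr);
  arma::fmat dWf = dY.t() * cols;
  arma::mat Wd(Wm.begin(), Cout, Wm.ncol(), false);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wd);
  arma::fmat dcols = dY * Wf;
  NumericVector dx((long)V * C);
  std::fill(dx.begin(), dx.end(), 0.0);
  col2im3f(dcols, dx.begin(), D, H, W, C, k, dil);
  dx.attr("dim") = IntegerVector::create(D, H, W, C);
  arma::rowvec db = arma::sum(dYd, 0);
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(arma::conv_to<arma::mat>::from(dWf)),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// forward that also returns the patch matrix for reuse in the backward pass
// [[Rcpp::export]]
List cpp_conv3_fwc(NumericVector x, IntegerVector dims,
                   NumericMatrix Wm, NumericVector b, int k, int dil) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Cout = Wm.nrow();
  if (Wm.ncol() != k * k * k * C) stop("kernel/channel mismatch in conv3");
  const long V = (long)D * H * W;
  arma::mat cols = im2col3(x.begin(), D, H, W, C, k, dil);
  arma::mat Wa(Wm.begin(), Cout, Wm.ncol(), false);
  NumericVector out((long)V * Cout);
  arma::mat Y(out.begin(), V, Cout, false, true);
  Y = cols * Wa.t();
  Y.each_row() += arma::rowvec(b.begin(), Cout);
  out.attr("dim") = IntegerVector::create(D, H, W, Cout);
  XPtr<arma::mat> ptr(new arma::mat(std::move(cols)), true);
  return List::create(_["y"] = out, _["cols"] = ptr);
}

// backward reusing a cached patch matrix (V x 27C, held as external ptr)
// [[Rcpp::export]]
List cpp_conv3_bwc(SEXP colsPtr, IntegerVector dims,
                   NumericMatrix Wm, NumericVector dy, int k, int dil) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Cout = Wm.nrow();
  const long V = (long)D * H * W;
  arma::mat dY(dy.begin(), V, Cout, false);
  arma::mat& cols = *XPtr<arma::mat>(colsPtr);
  arma::mat dW = dY.t() * cols;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat Wa(Wm.begin(), Cout, Wm.ncol(), false);
  arma::mat dcols = dY * Wa;
  NumericVector dx((long)V * C);
  std::fill(dx.begin(), dx.end(), 0.0);
  col2im3(dcols, dx.begin(), D, H, W, C, k, dil);
  dx.attr("dim") = IntegerVector::create(D, H, W, C);
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List cpp_conv3_bw(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                  NumericVector dy, int k, int dil) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Cout = Wm.nrow();
  const long V = (long)D * H * W;
  arma::mat dY(dy.begin(), V, Cout, false);      // V x Cout
  arma::mat cols = im2col3(x.begin(), D, H, W, C, k, dil);
  arma::mat dW = dY.t() * cols;                  // Cout x 27C
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat Wa(Wm.begin(), Cout, Wm.ncol(), false);
  arma::mat dcols = dY * Wa;                     // V x 27C
  NumericVector dx((long)V * C);
  std::fill(dx.begin(), dx.end(), 0.0);
  col2im3(dcols, dx.begin(), D, H, W, C, k, dil);
  dx.attr("dim") = IntegerVector::create(D, H, W, C);
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// depthwise: one k^3 kernel per channel, Wd is (k^3 x C)
// [[Rcpp::export]]
NumericVector cpp_dwconv3_fw(NumericVector x, IntegerVector dims,
                             NumericMatrix Wd, NumericVector b, int k, int dil) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  if (Wd.ncol() != C || Wd.nrow() != k * k * k) stop("kernel/channel mismatch in dwconv3");
  const int p = dil * (k - 1) / 2;
  const long V = (long)D * H * W;
  NumericVector out((long)V * C);
  std::fill(out.begin(), out.end(), 0.0);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (long)c * V;
    double* yc = out.begin() + (long)c * V;
    const double bc = b[c];
    for (long v = 0; v < V; ++v) yc[v] = bc;
    for (int kw = 0; kw < k; ++kw) {
      const int ow = kw * dil - p;
      for (int kh = 0; kh < k; ++kh) {
        const int oh = kh * dil - p;
        for (int kd = 0; kd < k; ++kd) {
          const int od = kd * dil - p;
          const double wv = Wd(kd + k * kh + k * k * kw, c);
          if (wv == 0.0) continue;
          for (int w = 0; w < W; ++w) {
            const int sw = w + ow;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + oh;
              if (sh < 0 || sh >= H) continue;
              const int d0 = std::max(0, -od);
              const int d1 = std::min(D, D - od);
              const double* src = xc + d0 + od + (long)D * (sh + (long)H * sw);
              double* dst = yc + d0 + (long)D * (h + (long)H * w);
              for (int d = d0; d < d1; ++d) dst[d - d0] += wv * src[d - d0];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(D, H, W, C);
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv3_bw(NumericVector x, IntegerVector dims, NumericMatrix Wd,
                    NumericVector dy, int k, int dil) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int p = dil * (k - 1) / 2;
  const long V = (long)D * H * W;
  NumericVector dx((long)V * C);
  std::fill(dx.begin(), dx.end(), 0.0);
  NumericMatrix dW(k * k * k, C);
  NumericVector db(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (long)c * V;
    const double* gc = dy.begin() + (long)c * V;
    double* dxc = dx.begin() + (long)c * V;
    double s = 0.0;
    for (long v = 0; v < V; ++v) s += gc[v];
    db[c] = s;
    for (int kw = 0; kw < k; ++kw) {
      const int ow = kw * dil - p;
      for (int kh = 0; kh < k; ++kh) {
        const int oh = kh * dil - p;
        for (int kd = 0; kd < k; ++kd) {
          const int od = kd * dil - p;
          const double wv = Wd(kd + k * kh + k * k * kw, c);
          double acc = 0.0;
          for (int w = 0; w < W; ++w) {
            const int sw = w + ow;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + oh;
              if (sh < 0 || sh >= H) continue;
              const int d0 = std::max(0, -od);
              const int d1 = std::min(D, D - od);
              const double* src = xc + d0 + od + (long)D * (sh + (long)H * sw);
              const double* g = gc + d0 + (long)D * (h + (long)H * w);
              double* dst = dxc + d0 + od + (long)D * (sh + (long)H * sw);
              for (int d = 0; d < d1 - d0; ++d) {
                acc += src[d] * g[d];
                dst[d] += wv * g[d];
              }
            }
          }
          dW(kd + k * kh + k * k * kw, c) += acc;
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(D, H, W, C);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// directed mean of minimum Euclidean distances from points A to points B.
// pts are n x 3 matrices of 0-based voxel coordinates; spacing is length 3 (mm).
// [[Rcpp::export]]
double cpp_mean_min_dist(NumericMatrix A, NumericMatrix B, NumericVector spacing) {
  const int nA = A.nrow(), nB = B.nrow();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double total = 0.0;
  for (int i = 0; i < nA; ++i) {
    const double ax = A(i, 0) * sx, ay = A(i, 1) * sy, az = A(i, 2) * sz;
    double best = R_PosInf;
    for (int j = 0; j < nB; ++j) {
      const double dx = ax - B(j, 0) * sx;
      const double dy = ay - B(j, 1) * sy;
      const double dz = az - B(j, 2) * sz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    total += std::sqrt(best);
  }
  return total / nA;
}
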