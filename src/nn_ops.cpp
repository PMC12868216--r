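// Convolutional primitives for the compact U-Net.
//
// Tensors are R arrays with dim (H, W, C, N), column-major, so sample n is
// a contiguous (H, W, C) block. Convolutions use "same" zero padding and
// an im2col + GEMM formulation; weights are R arrays with dim
// (k, k, Cin, Cout), which flatten column-major to a (k*k*Cin) x Cout
// matrix with row order (ky, kx, ci) fastest-first -- im2col below builds
// its rows in the same order.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static IntegerVector tensor_dim(const NumericVector& x, int ndim,
                                const char* what) {
  SEXP d = x.attr("dim");
  if (Rf_isNull(d)) stop("%s must be a dim-ed array", what);
  IntegerVector dims(d);
  if (dims.size() != ndim) stop("%s must have %d dimensions", what, ndim);
  return dims;
}

static void im2col(const arma::cube& X, int k, arma::mat& A) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int pad = (k - 1) / 2;
  A.zeros(k * k * C, H * W);
  for (int ci = 0; ci < C; ++ci) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int r = ky + k * kx + k * k * ci;
        for (int x = 0; x < W; ++x) {
          const int sx = x + kx - pad;
          if (sx < 0 || sx >= W) continue;
          for (int y = 0; y < H; ++y) {
            const int sy = y + ky - pad;
            if (sy < 0 || sy >= H) continue;
            A(r, y + x * H) = X(sy, sx, ci);
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& A, int k, arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int pad = (k - 1) / 2;
  for (int ci = 0; ci < C; ++ci) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int r = ky + k * kx + k * k * ci;
        for (int x = 0; x < W; ++x) {
          const int sx = x + kx - pad;
          if (sx < 0 || sx >= W) continue;
          for (int y = 0; y < H; ++y) {
            const int sy = y + ky - pad;
            if (sy < 0 || sy >= H) continue;
            X(sy, sx, ci) += A(r, y + x * H);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w,
                           NumericVector b) {
  IntegerVector xd = tensor_dim(x, 4, "x"), wd = tensor_dim(w, 4, "w");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("weight dims inconsistent with input");
  if (b.size() != Cout) stop("bias length must equal Cout");
  NumericVector y(static_cast<R_xlen_t>(H) * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout,
                     false, true);
  const arma::vec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat A;
  for (int n = 0; n < N; ++n) {
    const arma::cube Xc(const_cast<double*>(x.begin()) +
                        static_cast<size_t>(n) * H * W * Cin,
                        H, W, Cin, false, true);
    im2col(Xc, k, A);
    arma::mat Ym(y.begin() + static_cast<size_t>(n) * H * W * Cout,
                 H * W, Cout, false, true);
    Ym = A.t() * Wm;
    Ym.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = tensor_dim(x, 4, "x"), wd = tensor_dim(w, 4, "w");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * Cin * N);
  dx.attr("dim") = xd;
  NumericVector dw(static_cast<R_xlen_t>(k) * k * Cin * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout,
                     false, true);
  arma::mat dWm(dw.begin(), k * k * Cin, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat A;
  for (int n = 0; n < N; ++n) {
    const arma::cube Xc(const_cast<double*>(x.begin()) +
                        static_cast<size_t>(n) * H * W * Cin,
                        H, W, Cin, false, true);
    const arma::mat dYm(const_cast<double*>(dy.begin()) +
                        static_cast<size_t>(n) * H * W * Cout,
                        H * W, Cout, false, true);
    im2col(Xc, k, A);
    dWm += A * dYm;
    dbv += arma::sum(dYm, 0).t();
    arma::mat dA = Wm * dYm.t();
    arma::cube dXc(dx.begin() + static_cast<size_t>(n) * H * W * Cin,
                   H, W, Cin, false, true);
    col2im_add(dA, k, dXc);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  IntegerVector xd = tensor_dim(x, 4, "x");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool input dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // 0-based linear index into x
  idx.attr("dim") = y.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    const size_t base_n = static_cast<size_t>(n) * H * W * C;
    for (int c = 0; c < C; ++c) {
      const size_t base_c = base_n + static_cast<size_t>(c) * H * W;
      for (int xo = 0; xo < Wo; ++xo) {
        for (int yo = 0; yo < Ho; ++yo, ++o) {
          size_t best = base_c + (2 * yo) + static_cast<size_t>(2 * xo) * H;
          double bv = xp[best];
          const size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int j = 0; j < 3; ++j) {
            if (xp[cand[j]] > bv) { bv = xp[cand[j]]; best = cand[j]; }
          }
          yp[o] = bv;
          ip[o] = static_cast<int>(best);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector dy,
                              IntegerVector in_dim) {
  R_xlen_t total = 1;
  for (int i = 0; i < in_dim.size(); ++i) total *= in_dim[i];
  NumericVector dx(total);
  dx.attr("dim") = in_dim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  for (R_xlen_t o = 0; o < dy.size(); ++o) dxp[ip[o]] += dyp[o];
  return dx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x) {
  IntegerVector xd = tensor_dim(x, 4, "x");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t bi = (static_cast<size_t>(n) * C + c) * H * W;
      const size_t bo = (static_cast<size_t>(n) * C + c) * Ho * Wo;
      for (int xx = 0; xx < W; ++xx) {
        for (int yy = 0; yy < H; ++yy) {
          const double v = xp[bi + yy + static_cast<size_t>(xx) * H];
          const size_t o = bo + 2 * yy + static_cast<size_t>(2 * xx) * Ho;
          yp[o] = v; yp[o + 1] = v; yp[o + Ho] = v; yp[o + Ho + 1] = v;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector dy) {
  IntegerVector yd = tensor_dim(dy, 4, "dy");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t bi = (static_cast<size_t>(n) * C + c) * H * W;
      const size_t bo = (static_cast<size_t>(n) * C + c) * Ho * Wo;
      for (int xx = 0; xx < W; ++xx) {
        for (int yy = 0; yy < H; ++yy) {
          const size_t o = bo + 2 * yy + static_cast<size_t>(2 * xx) * Ho;
          dxp[bi + yy + static_cast<size_t>(xx) * H] =
            dyp[o] + dyp[o + 1] + dyp[o + Ho] + dyp[o + Ho + 1];
        }
      }
    }
  }
  return dx;
}
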