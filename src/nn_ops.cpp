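// Minimal dense kernels for small single-channel CNNs on connectivity
// matrices: same-padded 3x3 convolution and 2x2 max-pooling, forward and
// backward.  Tensors are R arrays in (H, W, C, N) layout (column-major, H
// fastest).  Convolution weights are (9*C_in) x C_out matrices with row
// index c*9 + k, where k enumerates the 3x3 offsets (dj+1)*3 + (di+1);
// fan-in is therefore 9*C_in.  The whole batch shares one im2col matrix
// (rows ordered position-fastest, sample-slowest) so each convolution is
// a single GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector alloc4(int H, int W, int C, int N) {
  NumericVector v((R_xlen_t)H * W * C * N);
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return v;
}

static IntegerVector alloc4i(int H, int W, int C, int N) {
  IntegerVector v((R_xlen_t)H * W * C * N);
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return v;
}

// writes sample n's patches into rows [row0, row0 + H*W) of col
static void im2col_3x3(const double* x, int H, int W, int C, arma::mat& col,
                       size_t row0) {
  const size_t plane = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + c * plane;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = (dj + 1) * 3 + (di + 1);
        double* colk = col.colptr(c * 9 + k) + row0;
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          double* dst = colk + (size_t)j * H;
          if (js < 0 || js >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)js * H;
          for (int i = 0; i < H; ++i) {
            const int is = i + di;
            dst[i] = (is >= 0 && is < H) ? src[is] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_3x3(const arma::mat& col, size_t row0, int H, int W,
                       int C, double* dx) {
  const size_t plane = (size_t)H * W;
  std::fill(dx, dx + plane * C, 0.0);
  for (int c = 0; c < C; ++c) {
    double* xc = dx + c * plane;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = (dj + 1) * 3 + (di + 1);
        const double* colk = col.colptr(c * 9 + k) + row0;
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const double* src = colk + (size_t)j * H;
          double* dst = xc + (size_t)js * H;
          for (int i = 0; i < H; ++i) {
            const int is = i + di;
            if (is >= 0 && is < H) dst[is] += src[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3x3_forward")]]
NumericVector conv3x3_forward(NumericVector x, NumericMatrix Wt,
                              NumericVector b) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = Wt.ncol();
  if (Wt.nrow() != 9 * C) stop("conv weight rows must equal 9*C_in");
  const size_t plane = (size_t)H * W;
  arma::mat Wm(Wt.begin(), Wt.nrow(), Cout, false);
  NumericVector out = alloc4(H, W, Cout, N);
  arma::mat col(plane * N, 9 * C);
  for (int n = 0; n < N; ++n)
    im2col_3x3(x.begin() + n * plane * C, H, W, C, col, n * plane);
  arma::mat o = col * Wm;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = o.colptr(co) + n * plane;
      double* dst = out.begin() + ((size_t)n * Cout + co) * plane;
      for (size_t q = 0; q < plane; ++q) dst[q] = src[q] + b[co];
    }
  return out;
}

// [[Rcpp::export(name = ".conv3x3_backward")]]
List conv3x3_backward(NumericVector x, NumericMatrix Wt, NumericVector dout) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = Wt.ncol();
  const size_t plane = (size_t)H * W;
  arma::mat Wm(Wt.begin(), Wt.nrow(), Cout, false);
  NumericVector dx = alloc4(H, W, C, N);
  arma::mat col(plane * N, 9 * C);
  arma::mat dom(plane * N, Cout);
  for (int n = 0; n < N; ++n) {
    im2col_3x3(x.begin() + n * plane * C, H, W, C, col, n * plane);
    for (int co = 0; co < Cout; ++co)
      std::copy(dout.begin() + ((size_t)n * Cout + co) * plane,
                dout.begin() + ((size_t)n * Cout + co + 1) * plane,
                dom.colptr(co) + n * plane);
  }
  arma::mat dW = col.t() * dom;
  arma::rowvec db = arma::sum(dom, 0);
  arma::mat dcol = dom * Wm.t();
  for (int n = 0; n < N; ++n)
    col2im_3x3(dcol, n * plane, H, W, C, dx.begin() + n * plane * C);
  return List::create(_["dx"] = dx,
                      _["dW"] = NumericMatrix(9 * C, Cout, dW.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;  // odd trailing row/col is dropped
  NumericVector out = alloc4(Ho, Wo, C, N);
  IntegerVector which = alloc4i(Ho, Wo, C, N);
  const size_t in_plane = (size_t)H * W;
  size_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * in_plane;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          const int i0 = 2 * i, j0 = 2 * j;
          double best = xc[i0 + (size_t)j0 * H];
          int bk = 0;
          const int ii[4] = {i0, i0 + 1, i0, i0 + 1};
          const int jj[4] = {j0, j0, j0 + 1, j0 + 1};
          for (int k = 1; k < 4; ++k) {
            const double v = xc[ii[k] + (size_t)jj[k] * H];
            if (v > best) { best = v; bk = k; }
          }
          out[q] = best;
          which[q] = bk;
          ++q;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(IntegerVector which, NumericVector dout,
                                int H, int W) {
  IntegerVector d = dout.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx = alloc4(H, W, C, N);
  const size_t in_plane = (size_t)H * W;
  size_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + ((size_t)n * C + c) * in_plane;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          const int k = which[q];
          const int is = 2 * i + (k % 2);
          const int js = 2 * j + (k / 2);
          xc[is + (size_t)js * H] += dout[q];
          ++q;
        }
      }
    }
  }
  return dx;
}
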