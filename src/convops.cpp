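// Low-level tensor kernels for the 2D U-Net: 3x3 same-padding convolution,
// 2x2 max pooling and 2x2 stride-2 up-convolution, each with forward and
// backward passes, implemented as im2col/col2im plus GEMM.
//
// Tensor layout is R column-major (H, W, C, N).  Convolution weights are
// stored as a (9*Cin) x Cout matrix with row index ki + 3*kj + 9*c
// (ki, kj in 0..2 over the kernel window, c the input channel); up-conv
// weights as a Cin x (4*Cout) matrix with column index ki + 2*kj + 4*co.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector makeArray4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}


static void im2col3(const double* x, int H, int W, int C, arma::mat& M) {
  // M: (H*W) x (9*C), zero-padded borders
  M.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        int col = (ki + 1) + 3 * (kj + 1) + 9 * c;
        double* Mcol = M.colptr(col);
        for (int j = 0; j < W; ++j) {
          int js = j + kj;
          if (js < 0 || js >= W) continue;
          int i0 = std::max(0, -ki), i1 = std::min(H, H - ki);
          const double* src = xc + (size_t)H * js + (i0 + ki);
          double* dst = Mcol + (size_t)H * j + i0;
          std::copy(src, src + (i1 - i0), dst);
        }
      }
    }
  }
}

static void col2im3(const arma::mat& M, int H, int W, int C, double* dx) {
  // adjoint of im2col3: accumulate into dx (H, W, C)
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        int col = (ki + 1) + 3 * (kj + 1) + 9 * c;
        const double* Mcol = M.colptr(col);
        for (int j = 0; j < W; ++j) {
          int js = j + kj;
          if (js < 0 || js >= W) continue;
          int i0 = std::max(0, -ki), i1 = std::min(H, H - ki);
          const double* src = Mcol + (size_t)H * j + i0;
          double* dst = xc + (size_t)H * js + (i0 + ki);
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2dForward(NumericVector x, NumericMatrix w, NumericVector b) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = w.ncol();
  if (w.nrow() != 9 * C) stop("weight rows != 9*Cin");
  arma::mat Wm(w.begin(), w.nrow(), Cout, false);
  NumericVector y = makeArray4(H, W, Cout, N);
  arma::mat M(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)H * W * C * n, H, W, C, M);
    arma::mat Y(y.begin() + (size_t)H * W * Cout * n, H * W, Cout, false, true);
    Y = M * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2dBackward(NumericVector x, NumericMatrix w, NumericVector dy) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = w.ncol();
  arma::mat Wm(w.begin(), w.nrow(), Cout, false);
  NumericVector dx = makeArray4(H, W, C, N);
  arma::mat dW(9 * C, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat M(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)H * W * C * n, H, W, C, M);
    arma::mat dY((double*)dy.begin() + (size_t)H * W * Cout * n, H * W, Cout, false, true);
    dW += M.t() * dY;
    db += arma::sum(dY, 0).t();
    arma::mat dM = dY * Wm.t();
    col2im3(dM, H, W, C, dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW), _["db"] = wrap(db));
}

// [[Rcpp::export(name = ".maxpool2Forward")]]
List maxpool2Forward(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = makeArray4(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int q = 0; q < C * N; ++q) {
    const double* xq = xp + (size_t)H * W * q;
    size_t off = (size_t)H * W * q;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        // scan order fixes argmax ties deterministically
        int cand[4] = {2 * i + H * 2 * j,     2 * i + 1 + H * 2 * j,
                       2 * i + H * (2 * j + 1), 2 * i + 1 + H * (2 * j + 1)};
        int best = cand[0];
        double bv = xq[cand[0]];
        for (int k = 1; k < 4; ++k)
          if (xq[cand[k]] > bv) { bv = xq[cand[k]]; best = cand[k]; }
        size_t o = (size_t)Ho * Wo * q + i + (size_t)Ho * j;
        yp[o] = bv;
        ip[o] = (int)(off + best);
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2Backward")]]
NumericVector maxpool2Backward(IntegerVector idx, NumericVector dy,
                               IntegerVector xdim) {
  NumericVector dx = makeArray4(xdim[0], xdim[1], xdim[2], xdim[3]);
  double* dxp = dx.begin();
  for (R_xlen_t k = 0; k < dy.size(); ++k) dxp[idx[k]] += dy[k];
  return dx;
}

// [[Rcpp::export(name = ".upconv2Forward")]]
NumericVector upconv2Forward(NumericVector x, NumericMatrix w, NumericVector b) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = w.ncol() / 4;
  if (w.nrow() != C) stop("up-conv weight rows != Cin");
  arma::mat Wm(w.begin(), C, 4 * Cout, false);
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = makeArray4(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X((double*)x.begin() + (size_t)H * W * C * n, H * W, C, false, true);
    arma::mat Y4 = X * Wm;  // (H*W) x (4*Cout)
    double* yn = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (size_t)Ho * Wo * co;
      for (int kj = 0; kj < 2; ++kj)
        for (int ki = 0; ki < 2; ++ki) {
          const double* col = Y4.colptr(ki + 2 * kj + 4 * co);
          for (int j = 0; j < W; ++j) {
            const double* src = col + (size_t)H * j;
            double* dst = yc + (size_t)Ho * (2 * j + kj) + ki;
            for (int i = 0; i < H; ++i) dst[2 * i] = src[i] + b[co];
          }
        }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upconv2Backward")]]
List upconv2Backward(NumericVector x, NumericMatrix w, NumericVector dy) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = w.ncol() / 4;
  arma::mat Wm(w.begin(), C, 4 * Cout, false);
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx = makeArray4(H, W, C, N);
  arma::mat dW(C, 4 * Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat dY4(H * W, 4 * Cout);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyn + (size_t)Ho * Wo * co;
      for (int kj = 0; kj < 2; ++kj)
        for (int ki = 0; ki < 2; ++ki) {
          double* col = dY4.colptr(ki + 2 * kj + 4 * co);
          for (int j = 0; j < W; ++j) {
            const double* src = dyc + (size_t)Ho * (2 * j + kj) + ki;
            double* dst = col + (size_t)H * j;
            for (int i = 0; i < H; ++i) { dst[i] = src[2 * i]; db[co] += src[2 * i]; }
          }
        }
    }
    arma::mat X((double*)x.begin() + (size_t)H * W * C * n, H * W, C, false, true);
    dW += X.t() * dY4;
    arma::mat dX(dx.begin() + (size_t)H * W * C * n, H * W, C, false, true);
    dX = dY4 * Wm.t();
  }
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW), _["db"] = wrap(db));
}

// Batch normalization over (H, W, N) per channel, one pass in C++ to avoid
// repeated array permutations on the R side.
// [[Rcpp::export(name = ".bnForwardCpp")]]
List bnForwardCpp(NumericVector x, NumericVector gamma, NumericVector beta,
                  NumericVector rmean, NumericVector rvar, bool training,
                  double momentum, double eps) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t HW = (size_t)H * W, stride = HW * C;
  NumericVector y = makeArray4(H, W, C, N);
  NumericVector xhat = makeArray4(H, W, C, N);
  NumericVector mu(C), va(C), invstd(C);
  NumericVector newMean = clone(rmean), newVar = clone(rvar);
  double M = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double m = rmean[c], v = rvar[c];
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + stride * n + HW * c;
        for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
      newMean[c] = (1 - momentum) * rmean[c] + momentum * m;
      newVar[c] = (1 - momentum) * rvar[c] + momentum * v;
    }
    mu[c] = m; va[c] = v;
    double is = 1.0 / std::sqrt(v + eps);
    invstd[c] = is;
    double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + stride * n + HW * c;
      double* xh = xhat.begin() + stride * n + HW * c;
      double* yp = y.begin() + stride * n + HW * c;
      for (size_t i = 0; i < HW; ++i) {
        double z = (p[i] - m) * is;
        xh[i] = z;
        yp[i] = g * z + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["mean"] = newMean, _["var"] = newVar);
}

// [[Rcpp::export(name = ".bnBackwardCpp")]]
List bnBackwardCpp(NumericVector dy, NumericVector xhat, NumericVector invstd,
                   NumericVector gamma, bool training) {
  IntegerVector d = dy.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t HW = (size_t)H * W, stride = HW * C;
  NumericVector dx = makeArray4(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  double M = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double sd = 0, sdx = 0;
    for (int n = 0; n < N; ++n) {
      const double* pdy = dy.begin() + stride * n + HW * c;
      const double* pxh = xhat.begin() + stride * n + HW * c;
      for (size_t i = 0; i < HW; ++i) {
        sd += pdy[i];
        sdx += pdy[i] * pxh[i];
      }
    }
    dgamma[c] = sdx;
    dbeta[c] = sd;
    double g = gamma[c], is = invstd[c];
    double mdx = g * sd / M, mdxx = g * sdx / M;
    for (int n = 0; n < N; ++n) {
      const double* pdy = dy.begin() + stride * n + HW * c;
      const double* pxh = xhat.begin() + stride * n + HW * c;
      double* pdx = dx.begin() + stride * n + HW * c;
      if (training)
        for (size_t i = 0; i < HW; ++i)
          pdx[i] = is * (g * pdy[i] - mdx - pxh[i] * mdxx);
      else
        for (size_t i = 0; i < HW; ++i)
          pdx[i] = is * g * pdy[i];
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
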