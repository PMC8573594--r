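// Convolution kernels: im2col + BLAS matrix products with tight scatter /
// gather loops. Batches are (H, W, C, N) column-major arrays; im2col rows
// are ordered (ho, wo, n) with ho fastest, columns (kh, kw, ci) with kh
// fastest, matching the R-side weight reshape.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List conv2d_fw_cpp(NumericVector x, NumericVector w, NumericVector b,
                   int pad, bool want_col) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  const int rows = Ho * Wo * N, cols = k * k * Cin;

  arma::mat M(rows, cols);
  const double* xp = x.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * kw + k * k * ci;
        double* mcol = M.colptr(col);
        for (int n = 0; n < N; ++n) {
          const double* xn = xp + (std::size_t)(ci + Cin * n) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wsrc = wo + kw - pad;
            double* dst = mcol + (std::size_t)(n * Wo + wo) * Ho;
            if (wsrc < 0 || wsrc >= W) {
              std::fill(dst, dst + Ho, 0.0);
              continue;
            }
            const double* src = xn + (std::size_t)wsrc * H;
            // valid ho range: 0 <= ho + kh - pad < H
            int lo = std::max(0, pad - kh);
            int hi = std::min(Ho, H + pad - kh);
            for (int ho = 0; ho < lo; ++ho) dst[ho] = 0.0;
            for (int ho = lo; ho < hi; ++ho) dst[ho] = src[ho + kh - pad];
            for (int ho = hi; ho < Ho; ++ho) dst[ho] = 0.0;
          }
        }
      }
    }
  }
  const arma::mat Wm(const_cast<double*>(w.begin()), cols, Cout, false, true);
  arma::mat Y = M * Wm;
  if (b.size() == (R_xlen_t)Cout)
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];

  NumericVector y(Ho * Wo * Cout * (std::size_t)N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* yp = y.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* ycol = Y.colptr(co);
    for (int n = 0; n < N; ++n) {
      double* dst = yp + ((std::size_t)(co + Cout * n)) * Ho * Wo;
      const double* src = ycol + (std::size_t)n * Ho * Wo;
      std::copy(src, src + Ho * Wo, dst);
    }
  }
  if (want_col)
    return List::create(_["y"] = y, _["M"] = wrap(M));
  return List::create(_["y"] = y);
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericMatrix Min, NumericVector dy, NumericVector w,
                   IntegerVector xdim, int pad) {
  IntegerVector dd = dy.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int Ho = dd[0], Wo = dd[1], Cout = dd[2], N = dd[3];
  const int k = wd[0], Cin = wd[2];
  const int H = xdim[0], W = xdim[1];
  const int rows = Ho * Wo * N, cols = k * k * Cin;

  // permute dy (Ho, Wo, Cout, N) into (rows ordered ho,wo,n) x Cout
  arma::mat D(rows, Cout);
  const double* dyp = dy.begin();
  for (int co = 0; co < Cout; ++co) {
    double* dcol = D.colptr(co);
    for (int n = 0; n < N; ++n) {
      const double* src = dyp + ((std::size_t)(co + Cout * n)) * Ho * Wo;
      std::copy(src, src + Ho * Wo, dcol + (std::size_t)n * Ho * Wo);
    }
  }
  const arma::mat M(const_cast<double*>(Min.begin()), rows, cols, false, true);
  const arma::mat Wm(const_cast<double*>(w.begin()), cols, Cout, false, true);
  arma::mat gW = M.t() * D;
  arma::rowvec gb = arma::sum(D, 0);
  arma::mat dXcol = D * Wm.t();   // (rows, k*k*Cin)

  NumericVector dx((std::size_t)H * W * Cin * N);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * kw + k * k * ci;
        const double* mcol = dXcol.colptr(col);
        for (int n = 0; n < N; ++n) {
          double* xn = dxp + (std::size_t)(ci + Cin * n) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wsrc = wo + kw - pad;
            if (wsrc < 0 || wsrc >= W) continue;
            const double* src = mcol + (std::size_t)(n * Wo + wo) * Ho;
            double* dst = xn + (std::size_t)wsrc * H;
            int lo = std::max(0, pad - kh);
            int hi = std::min(Ho, H + pad - kh);
            for (int ho = lo; ho < hi; ++ho) dst[ho + kh - pad] += src[ho];
          }
        }
      }
    }
  }
  NumericVector gWv(wrap(arma::vectorise(gW)));
  gWv.attr("dim") = wd;
  return List::create(_["gW"] = gWv, _["gb"] = wrap(arma::vectorise(gb)),
                      _["dx"] = dx);
}

// batch-norm forward helper: given x (H, W, C, N) returns per-channel sums
// and sums of squares (the R side does the rest cheaply).
// [[Rcpp::export]]
List bn_moments_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector s(C), ss(C);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = xp + (std::size_t)(c + C * n) * H * W;
      double a = 0, b = 0;
      for (int i = 0; i < H * W; ++i) { a += p[i]; b += p[i] * p[i]; }
      s[c] += a; ss[c] += b;
    }
  return List::create(_["sum"] = s, _["sumsq"] = ss);
}

// y = (x - mu) * g + d per channel, fused (used for BN affine transforms)
// [[Rcpp::export]]
NumericVector bn_affine_cpp(NumericVector x, NumericVector mu,
                            NumericVector g, NumericVector d) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((std::size_t)H * W * C * N);
  y.attr("dim") = xd;
  const double* xp = x.begin(); double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)(c + C * n) * H * W;
      const double m = mu[c], gg = g[c], dd2 = d[c];
      for (int i = 0; i < H * W; ++i) yp[off + i] = (xp[off + i] - m) * gg + dd2;
    }
  return y;
}

// per-channel sums of a and a*b (BN backward reductions)
// [[Rcpp::export]]
List bn_reduce_cpp(NumericVector a, NumericVector b) {
  IntegerVector xd = a.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector s1(C), s2(C);
  const double* ap = a.begin(); const double* bp = b.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)(c + C * n) * H * W;
      double x1 = 0, x2 = 0;
      for (int i = 0; i < H * W; ++i) {
        x1 += ap[off + i];
        x2 += ap[off + i] * bp[off + i];
      }
      s1[c] += x1; s2[c] += x2;
    }
  return List::create(_["sum"] = s1, _["sumprod"] = s2);
}
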