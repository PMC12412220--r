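// Hot-path tensor ops for the residual networks: 2-D (grouped) convolution
// and max pooling, forward and backward, plus a fused SGD step. Tensors are
// numeric arrays with dim c(H, W, C, N), column-major, so x(i,j,c,n) sits at
// i + H*(j + W*(c + C*n)). Convolution weights have dim
// c(k, k, C_in/groups, C_out). The forward pass lowers the whole batch of
// one channel group to an im2col matrix (k*k*Cg rows, Ho*Wo*N columns) and
// multiplies once with BLAS; the backward pass reuses the lowering for dW
// and scatters W * dY back through col2im for dX.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill P (k*k*Cg rows x Ho*Wo*N cols) with patches of channel group g for
// the whole batch. Row layout matches the flattened weight:
// ki + k*kj + k*k*ci; column layout: oi + Ho*(oj + Wo*n).
static void im2col_batch(const double* x, int H, int W, int C, int N,
                         int c0, int Cg, int k, int stride, int pad,
                         int Ho, int Wo, arma::mat& P) {
  if (pad > 0) P.zeros();
  const size_t HoWo = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    for (int ci = 0; ci < Cg; ++ci) {
      const double* xc = x + (size_t)(n * C + c0 + ci) * H * W;
      const int rbase = k * k * ci;
      for (int oj = 0; oj < Wo; ++oj) {
        const int j0 = oj * stride - pad;
        for (int kj = 0; kj < k; ++kj) {
          const int j = j0 + kj;
          if (j < 0 || j >= W) continue;
          const double* xcol = xc + (size_t)H * j;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i0 = oi * stride - pad;
            const size_t col = (size_t)oi + Ho * oj + HoWo * n;
            double* pcol = P.colptr(col) + rbase + k * kj;
            for (int ki = 0; ki < k; ++ki) {
              const int i = i0 + ki;
              if (i < 0 || i >= H) continue;
              pcol[ki] = xcol[i];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cg = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("non-square kernel");
  if (C != Cg * groups) stop("channel/group mismatch");
  int Coutg = Cout / groups;
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("output would be empty");
  const size_t HoWo = (size_t)Ho * Wo;

  NumericVector y(HoWo * (size_t)Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat P(k * k * Cg, HoWo * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int g = 0; g < groups; ++g) {
    im2col_batch(xp, H, W, C, N, g * Cg, Cg, k, stride, pad, Ho, Wo, P);
    arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)g * Coutg * k * k * Cg,
                 k * k * Cg, Coutg, false, true);
    arma::mat Y = P.t() * Wm;  // (HoWo*N) x Coutg
    for (int co = 0; co < Coutg; ++co) {
      const double* src = Y.colptr(co);
      for (int n = 0; n < N; ++n)
        std::copy(src + HoWo * n, src + HoWo * (n + 1),
                  yp + ((size_t)n * Cout + g * Coutg + co) * HoWo);
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cg = wd[2], Cout = wd[3];
  int Coutg = Cout / groups;
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  const size_t HoWo = (size_t)Ho * Wo;

  NumericVector dx(x.size()), dw(w.size());
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat P(k * k * Cg, HoWo * N);
  arma::mat dYm(HoWo * N, Coutg);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int g = 0; g < groups; ++g) {
    im2col_batch(xp, H, W, C, N, g * Cg, Cg, k, stride, pad, Ho, Wo, P);
    for (int co = 0; co < Coutg; ++co) {
      double* dst = dYm.colptr(co);
      for (int n = 0; n < N; ++n) {
        const double* src = dyp + ((size_t)n * Cout + g * Coutg + co) * HoWo;
        std::copy(src, src + HoWo, dst + HoWo * n);
      }
    }
    arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)g * Coutg * k * k * Cg,
                 k * k * Cg, Coutg, false, true);
    arma::mat dWm(dw.begin() + (size_t)g * Coutg * k * k * Cg,
                  k * k * Cg, Coutg, false, true);
    dWm = P * dYm;
    arma::mat dP = Wm * dYm.t();  // (k2*Cg) x (HoWo*N)
    // col2im scatter-add
    for (int n = 0; n < N; ++n) {
      for (int ci = 0; ci < Cg; ++ci) {
        double* dxc = dxp + (size_t)(n * C + g * Cg + ci) * H * W;
        const int rbase = k * k * ci;
        for (int oj = 0; oj < Wo; ++oj) {
          const int j0 = oj * stride - pad;
          for (int kj = 0; kj < k; ++kj) {
            const int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            double* dxcol = dxc + (size_t)H * j;
            for (int oi = 0; oi < Ho; ++oi) {
              const int i0 = oi * stride - pad;
              const size_t col = (size_t)oi + Ho * oj + HoWo * n;
              const double* pcol = dP.colptr(col) + rbase + k * kj;
              for (int ki = 0; ki < k; ++ki) {
                const int i = i0 + ki;
                if (i < 0 || i >= H) continue;
                dxcol[i] += pcol[ki];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y(Ho * Wo * (size_t)C * N);
  IntegerVector arg(y.size());  // 0-based linear index into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)(n * C + c) * H * W;
      size_t base = (size_t)(n * C + c) * H * W;
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          int i0 = oi * stride - pad, j0 = oj * stride - pad;
          double best = R_NegInf;
          int bestIdx = -1;
          for (int kj = 0; kj < k; ++kj) {
            int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int i = i0 + ki;
              if (i < 0 || i >= H) continue;
              double v = xc[i + (size_t)H * j];
              if (v > best) { best = v; bestIdx = i + H * j; }
            }
          }
          size_t out = (size_t)oi + Ho * ((size_t)oj + Wo * ((size_t)c + (size_t)C * n));
          y[out] = best;
          arg[out] = (int)(base + bestIdx);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// Fused momentum-SGD step, in place: v = mom*v + g + wd*p; p -= lr*v.
// Caller guarantees p and v are not aliased elsewhere.
// [[Rcpp::export]]
void cpp_sgd_step(NumericVector p, NumericVector v, NumericVector g,
                  double lr, double mom, double wd) {
  double* pp = p.begin(); double* vp = v.begin(); const double* gp = g.begin();
  R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    vp[i] = mom * vp[i] + gp[i] + wd * pp[i];
    pp[i] -= lr * vp[i];
  }
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector arg, NumericVector dy, IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t t = 0; t < dy.size(); ++t) dx[arg[t]] += dy[t];
  return dx;
}
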