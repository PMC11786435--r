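// GEMM-based 2-D convolution (im2col) and batch-norm kernels for the
// network engine. Tensor layout follows R column-major arrays: activations
// are H x W x C x N, kernels are kh x kw x Cin x Cout. The im2col buffer is
// laid out (Ho*Wo) x (kh*kw*Cin) so both the buffer writes and the GEMM
// output land in contiguous memory.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// colsT: (Ho*Wo) x (kh*kw*C); column q = i + kh*j + kh*kw*c
static void im2colT(const double* x, int H, int W, int C,
                    int kh, int kw, int stride, int pad,
                    int Ho, int Wo, arma::mat& colsT) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        double* dst = colsT.colptr(i + kh * (j + kw * c));
        for (int wo = 0; wo < Wo; ++wo) {
          int wsrc = wo * stride + j - pad;
          double* d = dst + (std::size_t)Ho * wo;
          if (wsrc < 0 || wsrc >= W) {
            std::fill(d, d + Ho, 0.0);
            continue;
          }
          const double* s = xc + (std::size_t)H * wsrc;
          int ho = 0;
          // leading out-of-range rows
          for (; ho < Ho && ho * stride + i - pad < 0; ++ho) d[ho] = 0.0;
          if (stride == 1) {
            int hsrc = ho + i - pad;
            int nrun = std::min(Ho, H - (i - pad)) - ho;
            if (nrun > 0) std::copy(s + hsrc, s + hsrc + nrun, d + ho);
            ho += std::max(nrun, 0);
          } else {
            for (; ho < Ho; ++ho) {
              int hsrc = ho * stride + i - pad;
              if (hsrc >= H) break;
              d[ho] = s[hsrc];
            }
          }
          for (; ho < Ho; ++ho) d[ho] = 0.0;
        }
      }
    }
  }
}

static void col2imT_acc(const arma::mat& colsT, int H, int W, int C,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (std::size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const double* src = colsT.colptr(i + kh * (j + kw * c));
        for (int wo = 0; wo < Wo; ++wo) {
          int wsrc = wo * stride + j - pad;
          if (wsrc < 0 || wsrc >= W) continue;
          double* dcol = xc + (std::size_t)H * wsrc;
          const double* s = src + (std::size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int hsrc = ho * stride + i - pad;
            if (hsrc < 0 || hsrc >= H) continue;
            dcol[hsrc] += s[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;

  NumericVector y((std::size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat Wm(w.begin(), kh * kw * Cin, Cout, false, true);
  arma::mat colsT((std::size_t)Ho * Wo, kh * kw * Cin);
  arma::rowvec bias(b.begin(), Cout, false, true);

  for (int n = 0; n < N; ++n) {
    im2colT(x.begin() + (std::size_t)H * W * C * n, H, W, C,
            kh, kw, stride, pad, Ho, Wo, colsT);
    arma::mat yn(y.begin() + (std::size_t)Ho * Wo * Cout * n,
                 (std::size_t)Ho * Wo, Cout, false, true);
    yn = colsT * Wm;
    yn.each_row() += bias;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad, bool need_dx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];

  NumericVector dw((std::size_t)kh * kw * Cin * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((std::size_t)H * W * C * N);
    dx.attr("dim") = xd;
  }

  arma::mat Wm(w.begin(), kh * kw * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), kh * kw * Cin, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat colsT((std::size_t)Ho * Wo, kh * kw * Cin);

  for (int n = 0; n < N; ++n) {
    im2colT(x.begin() + (std::size_t)H * W * C * n, H, W, C,
            kh, kw, stride, pad, Ho, Wo, colsT);
    arma::mat dyn(dy.begin() + (std::size_t)Ho * Wo * Cout * n,
                  (std::size_t)Ho * Wo, Cout, false, true);
    dWm += colsT.t() * dyn;
    dbv += arma::sum(dyn, 0);
    if (need_dx) {
      arma::mat dcolsT = dyn * Wm.t();
      col2imT_acc(dcolsT, H, W, C, kh, kw, stride, pad, Ho, Wo,
                  dx.begin() + (std::size_t)H * W * C * n);
    }
  }
  return List::create(_["dx"] = need_dx ? (SEXP)dx : R_NilValue,
                      _["dw"] = dw, _["db"] = db);
}

// Per-channel mean and biased variance over H, W and N.
// [[Rcpp::export(name = ".bn_stats")]]
List bn_stats_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + (std::size_t)HW * (c + (std::size_t)C * n);
      for (int i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double m = s / ((double)HW * N);
    mean[c] = m;
    double v = s2 / ((double)HW * N) - m * m;
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = x * scale[c] + shift[c]
// [[Rcpp::export(name = ".bn_apply")]]
NumericVector bn_apply_cpp(NumericVector x, NumericVector scale,
                           NumericVector shift) {
  IntegerVector xd = x.attr("dim");
  int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector y((std::size_t)HW * C * N);
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      std::size_t off = (std::size_t)HW * (c + (std::size_t)C * n);
      const double* p = x.begin() + off;
      double* q = y.begin() + off;
      double a = scale[c], bsh = shift[c];
      for (int i = 0; i < HW; ++i) q[i] = p[i] * a + bsh;
    }
  return y;
}

// Training-mode batch-norm backward; xhat recomputed from x, mean, var.
// [[Rcpp::export(name = ".bn_backward_train")]]
List bn_backward_train_cpp(NumericVector x, NumericVector dy,
                           NumericVector gamma, NumericVector mean,
                           NumericVector var, double eps) {
  IntegerVector xd = x.attr("dim");
  int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  double m = (double)HW * N;
  NumericVector dx((std::size_t)HW * C * N), dgamma(C), dbeta(C);
  dx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double mu = mean[c], g = gamma[c];
    double s1 = 0, s2 = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      std::size_t off = (std::size_t)HW * (c + (std::size_t)C * n);
      const double* px = x.begin() + off;
      const double* pd = dy.begin() + off;
      for (int i = 0; i < HW; ++i) {
        double xh = (px[i] - mu) * inv;
        s1 += pd[i];            // sum dy
        s2 += pd[i] * xh;       // sum dy * xhat
        sb += pd[i];
      }
    }
    dgamma[c] = s2;
    dbeta[c] = sb;
    double t1 = s1 / m, t2 = s2 / m;
    for (int n = 0; n < N; ++n) {
      std::size_t off = (std::size_t)HW * (c + (std::size_t)C * n);
      const double* px = x.begin() + off;
      const double* pd = dy.begin() + off;
      double* pq = dx.begin() + off;
      for (int i = 0; i < HW; ++i) {
        double xh = (px[i] - mu) * inv;
        pq[i] = g * inv * (pd[i] - t1 - xh * t2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
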