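// 3D convolution primitives for the multi-task reconstruction network.
//
// Tensor layout: 5-D R arrays with dim = c(W, H, D, C, N), column-major,
// so linear index = w + W*(h + H*(d + D*(c + C*n))).  W is the fastest
// axis.  Kernels are cubic (k x k x k) with a single spatial stride and
// symmetric zero padding.  Weights are R matrices of shape Co x (Ci*k^3)
// with column index r = kw + k*(kh + k*(kd + k*ci)).
//
// Forward, backward-data and backward-filter are all expressed through
// im2col / col2im plus a BLAS gemm (via Armadillo).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Dims5 {
  int W, H, D, C, N;
};

static Dims5 get_dims(const NumericVector &x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 5) stop("expected a 5-D tensor (W,H,D,C,N)");
  Dims5 s;
  s.W = d[0]; s.H = d[1]; s.D = d[2]; s.C = d[3]; s.N = d[4];
  return s;
}

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather one sample into a (C*k^3) x (Wo*Ho*Do) column matrix.
static void im2col(const double *x, const Dims5 &s, int n, int k, int stride,
                   int pad, int Wo, int Ho, int Do, arma::mat &col) {
  const long sampOff = (long)n * s.C * s.D * s.H * s.W;
  for (int c = 0; c < s.C; ++c) {
    const double *xc = x + sampOff + (long)c * s.D * s.H * s.W;
    for (int kd = 0; kd < k; ++kd) {
      for (int kh = 0; kh < k; ++kh) {
        for (int kw = 0; kw < k; ++kw) {
          int r = kw + k * (kh + k * (kd + k * c));
          double *dst = col.colptr(0) + r; // stride col.n_rows between cols
          long m = 0;
          for (int dd = 0; dd < Do; ++dd) {
            int d_in = dd * stride + kd - pad;
            bool dok = (d_in >= 0 && d_in < s.D);
            for (int hh = 0; hh < Ho; ++hh) {
              int h_in = hh * stride + kh - pad;
              bool hok = dok && (h_in >= 0 && h_in < s.H);
              for (int ww = 0; ww < Wo; ++ww, ++m) {
                int w_in = ww * stride + kw - pad;
                double v = 0.0;
                if (hok && w_in >= 0 && w_in < s.W)
                  v = xc[(long)(d_in * s.H + h_in) * s.W + w_in];
                dst[m * col.n_rows] = v;
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add the adjoint of im2col.
static void col2im(const arma::mat &col, const Dims5 &s, int n, int k,
                   int stride, int pad, int Wo, int Ho, int Do, double *x) {
  const long sampOff = (long)n * s.C * s.D * s.H * s.W;
  for (int c = 0; c < s.C; ++c) {
    double *xc = x + sampOff + (long)c * s.D * s.H * s.W;
    for (int kd = 0; kd < k; ++kd) {
      for (int kh = 0; kh < k; ++kh) {
        for (int kw = 0; kw < k; ++kw) {
          int r = kw + k * (kh + k * (kd + k * c));
          const double *src = col.colptr(0) + r;
          long m = 0;
          for (int dd = 0; dd < Do; ++dd) {
            int d_in = dd * stride + kd - pad;
            bool dok = (d_in >= 0 && d_in < s.D);
            for (int hh = 0; hh < Ho; ++hh) {
              int h_in = hh * stride + kh - pad;
              bool hok = dok && (h_in >= 0 && h_in < s.H);
              for (int ww = 0; ww < Wo; ++ww, ++m) {
                int w_in = ww * stride + kw - pad;
                if (hok && w_in >= 0 && w_in < s.W)
                  xc[(long)(d_in * s.H + h_in) * s.W + w_in] +=
                      src[m * col.n_rows];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericMatrix w,
                             NumericVector b, int k, int stride, int pad) {
  Dims5 s = get_dims(x);
  int Co = w.nrow();
  int K = w.ncol();
  if (K != s.C * k * k * k) stop("weight shape does not match input channels");
  int Wo = out_size(s.W, k, stride, pad);
  int Ho = out_size(s.H, k, stride, pad);
  int Do = out_size(s.D, k, stride, pad);
  if (Wo < 1 || Ho < 1 || Do < 1) stop("input too small for this convolution");
  long M = (long)Wo * Ho * Do;

  NumericVector y((long)Wo * Ho * Do * Co * s.N);
  y.attr("dim") = IntegerVector::create(Wo, Ho, Do, Co, s.N);

  arma::mat Wm(w.begin(), Co, K, false, true);
  arma::mat col(K, M);
  for (int n = 0; n < s.N; ++n) {
    im2col(x.begin(), s, n, k, stride, pad, Wo, Ho, Do, col);
    arma::mat Y = Wm * col; // Co x M
    double *yp = y.begin() + (long)n * Co * M;
    for (int c = 0; c < Co; ++c) {
      double bias = b[c];
      for (long m = 0; m < M; ++m) yp[(long)c * M + m] = Y(c, m) + bias;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_data(NumericVector dy, NumericMatrix w, int k,
                                  int stride, int pad, IntegerVector in_dims) {
  Dims5 so = get_dims(dy); // gradient at the conv output
  int Co = w.nrow();
  if (so.C != Co) stop("dy channels do not match weights");
  int K = w.ncol();
  Dims5 s;
  s.W = in_dims[0]; s.H = in_dims[1]; s.D = in_dims[2];
  s.C = K / (k * k * k); s.N = so.N;
  if (out_size(s.W, k, stride, pad) != so.W ||
      out_size(s.H, k, stride, pad) != so.H ||
      out_size(s.D, k, stride, pad) != so.D)
    stop("in_dims inconsistent with dy under this kernel/stride/pad");
  long M = (long)so.W * so.H * so.D;

  NumericVector dx((long)s.W * s.H * s.D * s.C * s.N);
  dx.attr("dim") = IntegerVector::create(s.W, s.H, s.D, s.C, s.N);
  std::fill(dx.begin(), dx.end(), 0.0);

  arma::mat Wm(w.begin(), Co, K, false, true);
  for (int n = 0; n < s.N; ++n) {
    arma::mat dY(Co, M);
    const double *dyp = dy.begin() + (long)n * Co * M;
    for (int c = 0; c < Co; ++c)
      for (long m = 0; m < M; ++m) dY(c, m) = dyp[(long)c * M + m];
    arma::mat dcol = Wm.t() * dY; // K x M
    col2im(dcol, s, n, k, stride, pad, so.W, so.H, so.D, dx.begin());
  }
  return dx;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3d_bwd_filter(NumericVector x, NumericVector dy, int k,
                                    int stride, int pad) {
  Dims5 s = get_dims(x);
  Dims5 so = get_dims(dy);
  if (so.N != s.N) stop("batch mismatch");
  if (out_size(s.W, k, stride, pad) != so.W ||
      out_size(s.H, k, stride, pad) != so.H ||
      out_size(s.D, k, stride, pad) != so.D)
    stop("x and dy are inconsistent under this kernel/stride/pad");
  int Co = so.C;
  int K = s.C * k * k * k;
  long M = (long)so.W * so.H * so.D;

  arma::mat dW(Co, K, arma::fill::zeros);
  arma::mat col(K, M);
  for (int n = 0; n < s.N; ++n) {
    im2col(x.begin(), s, n, k, stride, pad, so.W, so.H, so.D, col);
    arma::mat dY(Co, M);
    const double *dyp = dy.begin() + (long)n * Co * M;
    for (int c = 0; c < Co; ++c)
      for (long m = 0; m < M; ++m) dY(c, m) = dyp[(long)c * M + m];
    dW += dY * col.t();
  }
  return wrap(dW);
}
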