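// 3D convolution primitives for the patch encoder.
//
// Layout convention (matches R column-major arrays):
//   input  x : dim c(d1, d2, d3, Cin,  N)
//   output y : dim c(o1, o2, o3, Cout, N)
//   weights  : K x Cout matrix with K = 27 * Cin, row index
//              r = di + 3*(dj + 3*(dk + 3*ci)), i.e. the column-major
//              flattening of an R array dim c(3, 3, 3, Cin, Cout).
// Kernel size is fixed at 3; stride and zero padding are parameters.
// The forward/backward pair uses im2col + GEMM per sample, which keeps the
// working set small while letting BLAS do the heavy lifting.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int outDim(int d, int pad, int stride) {
  return (d + 2 * pad - 3) / stride + 1;
}

// Fill the im2col matrix (K x M) for one sample.
static void im2col(const double* x, int d1, int d2, int d3, int cin,
                   int pad, int stride, int o1, int o2, int o3,
                   arma::mat& col) {
  const int M = o1 * o2 * o3;
  col.zeros();
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + (size_t)ci * d1 * d2 * d3;
    for (int dk = 0; dk < 3; ++dk) {
      for (int dj = 0; dj < 3; ++dj) {
        for (int di = 0; di < 3; ++di) {
          const int r = di + 3 * (dj + 3 * (dk + 3 * ci));
          for (int ko = 0; ko < o3; ++ko) {
            const int kin = ko * stride + dk - pad;
            if (kin < 0 || kin >= d3) continue;
            for (int jo = 0; jo < o2; ++jo) {
              const int jin = jo * stride + dj - pad;
              if (jin < 0 || jin >= d2) continue;
              const double* src =
                  xc + (size_t)kin * d1 * d2 + (size_t)jin * d1;
              const int vbase = o1 * (jo + o2 * ko);
              for (int io = 0; io < o1; ++io) {
                const int iin = io * stride + di - pad;
                if (iin < 0 || iin >= d1) continue;
                col.at(r, vbase + io) = src[iin];
              }
            }
          }
          (void)M;
        }
      }
    }
  }
}

// Scatter-add of a K x M gradient matrix back onto one input sample.
static void col2im(const arma::mat& col, int d1, int d2, int d3, int cin,
                   int pad, int stride, int o1, int o2, int o3, double* dx) {
  for (int ci = 0; ci < cin; ++ci) {
    double* xc = dx + (size_t)ci * d1 * d2 * d3;
    for (int dk = 0; dk < 3; ++dk) {
      for (int dj = 0; dj < 3; ++dj) {
        for (int di = 0; di < 3; ++di) {
          const int r = di + 3 * (dj + 3 * (dk + 3 * ci));
          for (int ko = 0; ko < o3; ++ko) {
            const int kin = ko * stride + dk - pad;
            if (kin < 0 || kin >= d3) continue;
            for (int jo = 0; jo < o2; ++jo) {
              const int jin = jo * stride + dj - pad;
              if (jin < 0 || jin >= d2) continue;
              double* dst = xc + (size_t)kin * d1 * d2 + (size_t)jin * d1;
              const int vbase = o1 * (jo + o2 * ko);
              for (int io = 0; io < o1; ++io) {
                const int iin = io * stride + di - pad;
                if (iin < 0 || iin >= d1) continue;
                dst[iin] += col.at(r, vbase + io);
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3dForward")]]
NumericVector conv3dForward(NumericVector x, IntegerVector xdim,
                            NumericMatrix w, NumericVector b,
                            int stride, int pad) {
  const int d1 = xdim[0], d2 = xdim[1], d3 = xdim[2];
  const int cin = xdim[3], n = xdim[4];
  const int K = 27 * cin;
  if (w.nrow() != K) stop("weight rows do not match 27 * Cin");
  const int cout = w.ncol();
  const int o1 = outDim(d1, pad, stride), o2 = outDim(d2, pad, stride),
            o3 = outDim(d3, pad, stride);
  const int M = o1 * o2 * o3;

  NumericVector y((size_t)M * cout * n);
  arma::mat wm(w.begin(), K, cout, false, true);
  arma::vec bv(b.begin(), cout, false, true);
  arma::mat col(K, M);
  const size_t xstr = (size_t)d1 * d2 * d3 * cin;
  const size_t ystr = (size_t)M * cout;

  for (int s = 0; s < n; ++s) {
    im2col(x.begin() + s * xstr, d1, d2, d3, cin, pad, stride, o1, o2, o3,
           col);
    arma::mat ym(y.begin() + s * ystr, M, cout, false, true);
    ym = col.t() * wm;
    ym.each_row() += bv.t();
  }
  y.attr("dim") = IntegerVector::create(o1, o2, o3, cout, n);
  return y;
}

// [[Rcpp::export(name = ".conv3dBackward")]]
List conv3dBackward(NumericVector x, IntegerVector xdim, NumericMatrix w,
                    NumericVector dy, int stride, int pad,
                    bool needDx) {
  const int d1 = xdim[0], d2 = xdim[1], d3 = xdim[2];
  const int cin = xdim[3], n = xdim[4];
  const int K = 27 * cin;
  const int cout = w.ncol();
  const int o1 = outDim(d1, pad, stride), o2 = outDim(d2, pad, stride),
            o3 = outDim(d3, pad, stride);
  const int M = o1 * o2 * o3;

  arma::mat wm(w.begin(), K, cout, false, true);
  arma::mat dw(K, cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  NumericVector dx(needDx ? x.size() : 0);
  arma::mat col(K, M);
  const size_t xstr = (size_t)d1 * d2 * d3 * cin;
  const size_t ystr = (size_t)M * cout;

  for (int s = 0; s < n; ++s) {
    im2col(x.begin() + s * xstr, d1, d2, d3, cin, pad, stride, o1, o2, o3,
           col);
    const arma::mat dym(const_cast<double*>(dy.begin()) + s * ystr, M, cout,
                        false, true);
    dw += col * dym;
    db += arma::sum(dym, 0).t();
    if (needDx) {
      arma::mat dcol = wm * dym.t();  // K x M
      col2im(dcol, d1, d2, d3, cin, pad, stride, o1, o2, o3,
             dx.begin() + s * xstr);
    }
  }
  List out = List::create(_["dW"] = wrap(dw), _["db"] = wrap(db));
  if (needDx) {
    dx.attr("dim") = xdim;
    out["dx"] = dx;
  }
  return out;
}
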