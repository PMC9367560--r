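// Fused multi-stage encoder forward/backward. Each stage: 3x3x3 convolution
// (stride 2, pad 1) + batch normalization + ReLU; after the last stage,
// global average pooling. The whole stage pipeline runs here so the large
// intermediates stay out of R's allocator; samples are processed in chunks
// whose im2col buffers feed one BLAS GEMM per chunk.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int CHUNK = 32;

static inline int outDim3(int d) { return (d + 2 - 3) / 2 + 1; }

// im2col for kernel 3, stride 2, pad 1, one sample, into columns
// [colOff, colOff + M) of col (K x M*chunk)
static void im2col32(const double* x, int d1, int d2, int d3, int cin,
                     int o1, int o2, int o3, arma::mat& col, int colOff) {
  const size_t cstr = col.n_rows;
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + (size_t)ci * d1 * d2 * d3;
    for (int dk = 0; dk < 3; ++dk) {
      for (int dj = 0; dj < 3; ++dj) {
        for (int di = 0; di < 3; ++di) {
          const int r = di + 3 * (dj + 3 * (dk + 3 * ci));
          const int io0 = (di == 0) ? 1 : 0;
          const int io1 = (2 * (o1 - 1) + di - 1 < d1) ? o1 : o1 - 1;
          const int jo0 = (dj == 0) ? 1 : 0;
          const int jo1 = (2 * (o2 - 1) + dj - 1 < d2) ? o2 : o2 - 1;
          const int ko0 = (dk == 0) ? 1 : 0;
          const int ko1 = (2 * (o3 - 1) + dk - 1 < d3) ? o3 : o3 - 1;
          for (int ko = ko0; ko < ko1; ++ko) {
            const int kin = 2 * ko + dk - 1;
            for (int jo = jo0; jo < jo1; ++jo) {
              const int jin = 2 * jo + dj - 1;
              const double* src = xc + (size_t)kin * d1 * d2 + (size_t)jin * d1;
              double* dst = col.colptr(colOff + o1 * (jo + o2 * ko)) + r;
              for (int io = io0; io < io1; ++io) {
                dst[(size_t)io * cstr] = src[2 * io + di - 1];
              }
            }
          }
        }
      }
    }
  }
}

static void col2im32(const arma::mat& col, int colOff, int d1, int d2, int d3,
                     int cin, int o1, int o2, int o3, double* dx) {
  const size_t cstr = col.n_rows;
  for (int ci = 0; ci < cin; ++ci) {
    double* xc = dx + (size_t)ci * d1 * d2 * d3;
    for (int dk = 0; dk < 3; ++dk) {
      for (int dj = 0; dj < 3; ++dj) {
        for (int di = 0; di < 3; ++di) {
          const int r = di + 3 * (dj + 3 * (dk + 3 * ci));
          const int io0 = (di == 0) ? 1 : 0;
          const int io1 = (2 * (o1 - 1) + di - 1 < d1) ? o1 : o1 - 1;
          const int jo0 = (dj == 0) ? 1 : 0;
          const int jo1 = (2 * (o2 - 1) + dj - 1 < d2) ? o2 : o2 - 1;
          const int ko0 = (dk == 0) ? 1 : 0;
          const int ko1 = (2 * (o3 - 1) + dk - 1 < d3) ? o3 : o3 - 1;
          for (int ko = ko0; ko < ko1; ++ko) {
            const int kin = 2 * ko + dk - 1;
            for (int jo = jo0; jo < jo1; ++jo) {
              const int jin = 2 * jo + dj - 1;
              double* dst = xc + (size_t)kin * d1 * d2 + (size_t)jin * d1;
              const double* src = col.colptr(colOff + o1 * (jo + o2 * ko)) + r;
              for (int io = io0; io < io1; ++io) {
                dst[2 * io + di - 1] += src[(size_t)io * cstr];
              }
            }
          }
        }
      }
    }
  }
}

struct StageDims {
  int d1, d2, d3, cin, o1, o2, o3, cout;
  size_t xstr, ystr;
};

static StageDims stageDims(IntegerVector xdim, int cout) {
  StageDims s;
  s.d1 = xdim[0]; s.d2 = xdim[1]; s.d3 = xdim[2]; s.cin = xdim[3];
  s.o1 = outDim3(s.d1); s.o2 = outDim3(s.d2); s.o3 = outDim3(s.d3);
  s.cout = cout;
  s.xstr = (size_t)s.d1 * s.d2 * s.d3 * s.cin;
  s.ystr = (size_t)s.o1 * s.o2 * s.o3 * s.cout;
  return s;
}

// chunked convolution forward: y (per sample M x cout blocks, channel-major)
static void convForward(const double* x, const StageDims& d, int n,
                        const arma::mat& wm, const arma::vec& bv, double* y) {
  const int M = d.o1 * d.o2 * d.o3;
  const int K = 27 * d.cin;
  const int ch = std::min(CHUNK, n);
  arma::mat col(K, (size_t)M * ch);
  arma::mat Y((size_t)M * ch, d.cout);
  for (int s0 = 0; s0 < n; s0 += ch) {
    const int nc = std::min(ch, n - s0);
    const size_t nCol = (size_t)M * nc;
    col.head_cols(nCol).zeros();
    for (int s = 0; s < nc; ++s) {
      im2col32(x + (size_t)(s0 + s) * d.xstr, d.d1, d.d2, d.d3, d.cin,
               d.o1, d.o2, d.o3, col, s * M);
    }
    Y.head_rows(nCol) = col.head_cols(nCol).t() * wm;
    Y.head_rows(nCol).each_row() += bv.t();
    for (int s = 0; s < nc; ++s) {
      for (int c = 0; c < d.cout; ++c) {
        std::memcpy(y + (size_t)(s0 + s) * d.ystr + (size_t)c * M,
                    Y.colptr(c) + (size_t)s * M, sizeof(double) * M);
      }
    }
  }
}

// chunked convolution backward: consumes dy (same layout as y)
static void convBackward(const double* x, const StageDims& d, int n,
                         const arma::mat& wm, const double* dy,
                         arma::mat& dW, arma::vec& db, double* dx,
                         bool wantDx) {
  const int M = d.o1 * d.o2 * d.o3;
  const int K = 27 * d.cin;
  const int ch = std::min(CHUNK, n);
  arma::mat col(K, (size_t)M * ch);
  arma::mat dyb((size_t)M * ch, d.cout);
  arma::mat dcol(K, (size_t)M * ch);
  for (int s0 = 0; s0 < n; s0 += ch) {
    const int nc = std::min(ch, n - s0);
    const size_t nCol = (size_t)M * nc;
    col.head_cols(nCol).zeros();
    for (int s = 0; s < nc; ++s) {
      im2col32(x + (size_t)(s0 + s) * d.xstr, d.d1, d.d2, d.d3, d.cin,
               d.o1, d.o2, d.o3, col, s * M);
      for (int c = 0; c < d.cout; ++c) {
        std::memcpy(dyb.colptr(c) + (size_t)s * M,
                    dy + (size_t)(s0 + s) * d.ystr + (size_t)c * M,
                    sizeof(double) * M);
      }
    }
    dW += col.head_cols(nCol) * dyb.head_rows(nCol);
    db += arma::sum(dyb.head_rows(nCol), 0).t();
    if (wantDx) {
      dcol.head_cols(nCol) = wm * dyb.head_rows(nCol).t();
      for (int s = 0; s < nc; ++s) {
        col2im32(dcol, s * M, d.d1, d.d2, d.d3, d.cin, d.o1, d.o2, d.o3,
                 dx + (size_t)(s0 + s) * d.xstr);
      }
    }
  }
}

// [[Rcpp::export(name = ".encForward")]]
List encForward(NumericVector x, IntegerVector xdim, List stages, List state,
                bool train, double momentum, double eps) {
  const int nStages = stages.size();
  const int n = xdim[4];
  List acts(nStages), xhats(nStages), invs(nStages), newState(nStages);
  NumericVector cur = x;
  IntegerVector cdim = clone(xdim);

  for (int st = 0; st < nStages; ++st) {
    List sp = stages[st];
    NumericMatrix W = sp["W"];
    NumericVector b = sp["b"], gamma = sp["gamma"], beta = sp["beta"];
    List stt = state[st];
    NumericVector rm = clone(as<NumericVector>(stt["rm"]));
    NumericVector rv = clone(as<NumericVector>(stt["rv"]));
    StageDims d = stageDims(cdim, W.ncol());
    const int M = d.o1 * d.o2 * d.o3;
    const int K = 27 * d.cin;

    NumericVector y((size_t)M * d.cout * n);
    arma::mat wm(W.begin(), K, d.cout, false, true);
    arma::vec bv(b.begin(), d.cout, false, true);
    convForward(cur.begin(), d, n, wm, bv, y.begin());

    // batch-norm statistics per channel
    const size_t m = (size_t)M * n;
    arma::vec mu(d.cout), va(d.cout);
    if (train) {
      mu.zeros(); va.zeros();
      for (int s = 0; s < n; ++s) {
        for (int c = 0; c < d.cout; ++c) {
          const double* yp = y.begin() + s * d.ystr + (size_t)c * M;
          double acc = 0, acc2 = 0;
          for (int v = 0; v < M; ++v) { acc += yp[v]; acc2 += yp[v] * yp[v]; }
          mu[c] += acc; va[c] += acc2;
        }
      }
      mu /= (double)m;
      va = va / (double)m - mu % mu;
      for (int c = 0; c < d.cout; ++c) {
        rm[c] = (1 - momentum) * rm[c] + momentum * mu[c];
        rv[c] = (1 - momentum) * rv[c] +
                momentum * va[c] * (double)m / std::max((double)m - 1, 1.0);
      }
    } else {
      for (int c = 0; c < d.cout; ++c) { mu[c] = rm[c]; va[c] = rv[c]; }
    }
    arma::vec inv = 1.0 / arma::sqrt(va + eps);

    // normalize + scale/shift + ReLU in one pass
    NumericVector xhat((size_t)M * d.cout * n);
    NumericVector act((size_t)M * d.cout * n);
    for (int s = 0; s < n; ++s) {
      for (int c = 0; c < d.cout; ++c) {
        const size_t off = s * d.ystr + (size_t)c * M;
        const double* yp = y.begin() + off;
        double* xp = xhat.begin() + off;
        double* ap = act.begin() + off;
        const double muc = mu[c], invc = inv[c], gc = gamma[c], bc = beta[c];
        for (int v = 0; v < M; ++v) {
          const double xh = (yp[v] - muc) * invc;
          xp[v] = xh;
          const double a = gc * xh + bc;
          ap[v] = a > 0 ? a : 0;
        }
      }
    }
    act.attr("dim") = IntegerVector::create(d.o1, d.o2, d.o3, d.cout, n);
    xhat.attr("dim") = act.attr("dim");
    acts[st] = act;
    xhats[st] = xhat;
    invs[st] = wrap(inv);
    newState[st] = List::create(_["rm"] = rm, _["rv"] = rv);
    cur = act;
    cdim = IntegerVector::create(d.o1, d.o2, d.o3, d.cout, n);
  }

  // global average pooling -> n x D
  const int D = cdim[3];
  const int Mlast = cdim[0] * cdim[1] * cdim[2];
  NumericMatrix feat(n, D);
  for (int s = 0; s < n; ++s) {
    for (int c = 0; c < D; ++c) {
      const double* ap = cur.begin() + (size_t)s * Mlast * D + (size_t)c * Mlast;
      double acc = 0;
      for (int v = 0; v < Mlast; ++v) acc += ap[v];
      feat(s, c) = acc / Mlast;
    }
  }
  return List::create(_["feat"] = feat, _["acts"] = acts, _["xhats"] = xhats,
                      _["invs"] = invs, _["state"] = newState);
}

// [[Rcpp::export(name = ".encBackward")]]
List encBackward(NumericVector x, IntegerVector xdim, List stages, List fwd,
                 NumericMatrix dfeat, bool train, bool needDx) {
  const int nStages = stages.size();
  const int n = xdim[4];
  List acts = fwd["acts"], xhats = fwd["xhats"], invs = fwd["invs"];
  List grads(nStages);

  std::vector<IntegerVector> dims(nStages + 1);
  dims[0] = clone(xdim);
  for (int st = 0; st < nStages; ++st) {
    List sp = stages[st];
    NumericMatrix W = sp["W"];
    StageDims d = stageDims(dims[st], W.ncol());
    dims[st + 1] = IntegerVector::create(d.o1, d.o2, d.o3, d.cout, n);
  }

  // GAP backward
  IntegerVector ld = dims[nStages];
  const int D = ld[3];
  const int Mlast = ld[0] * ld[1] * ld[2];
  NumericVector dcur((size_t)Mlast * D * n);
  for (int s = 0; s < n; ++s) {
    for (int c = 0; c < D; ++c) {
      double* dp = dcur.begin() + (size_t)s * Mlast * D + (size_t)c * Mlast;
      const double g = dfeat(s, c) / Mlast;
      for (int v = 0; v < Mlast; ++v) dp[v] = g;
    }
  }

  for (int st = nStages - 1; st >= 0; --st) {
    List sp = stages[st];
    NumericMatrix W = sp["W"];
    NumericVector gamma = sp["gamma"];
    StageDims d = stageDims(dims[st], W.ncol());
    const int M = d.o1 * d.o2 * d.o3;
    const int K = 27 * d.cin;
    const size_t m = (size_t)M * n;
    NumericVector act = acts[st], xhat = xhats[st];
    arma::vec inv = as<arma::vec>(invs[st]);

    // ReLU mask + BN channel sums in one pass
    arma::vec dgamma(d.cout, arma::fill::zeros),
              dbeta(d.cout, arma::fill::zeros);
    for (int s = 0; s < n; ++s) {
      for (int c = 0; c < d.cout; ++c) {
        const size_t off = s * d.ystr + (size_t)c * M;
        double* dp = dcur.begin() + off;
        const double* ap = act.begin() + off;
        const double* xp = xhat.begin() + off;
        double sg = 0, sb = 0;
        for (int v = 0; v < M; ++v) {
          const double dv = ap[v] > 0 ? dp[v] : 0;
          dp[v] = dv;                  // now holds d(bn out)
          sg += dv * xp[v];
          sb += dv;
        }
        dgamma[c] += sg;
        dbeta[c] += sb;
      }
    }
    // dxhat -> dy (conv output gradient), in place
    for (int s = 0; s < n; ++s) {
      for (int c = 0; c < d.cout; ++c) {
        const size_t off = s * d.ystr + (size_t)c * M;
        double* dp = dcur.begin() + off;
        const double* xp = xhat.begin() + off;
        const double gc = gamma[c], invc = inv[c];
        if (train) {
          const double s1 = gc * dbeta[c] / (double)m;
          const double s2 = gc * dgamma[c] / (double)m;
          for (int v = 0; v < M; ++v) {
            dp[v] = invc * (gc * dp[v] - s1 - xp[v] * s2);
          }
        } else {
          const double f = gc * invc;
          for (int v = 0; v < M; ++v) dp[v] *= f;
        }
      }
    }

    // conv backward (chunked GEMMs)
    const double* xin = (st == 0) ? x.begin()
                                  : as<NumericVector>(acts[st - 1]).begin();
    arma::mat wm(W.begin(), K, d.cout, false, true);
    arma::mat dW(K, d.cout, arma::fill::zeros);
    arma::vec db(d.cout, arma::fill::zeros);
    const bool wantDx = (st > 0) || needDx;
    NumericVector dxprev(wantDx ? (size_t)d.xstr * n : 0);
    convBackward(xin, d, n, wm, dcur.begin(), dW, db,
                 wantDx ? dxprev.begin() : nullptr, wantDx);
    grads[st] = List::create(_["W"] = wrap(dW), _["b"] = wrap(db),
                             _["gamma"] = wrap(arma::vec(dgamma)),
                             _["beta"] = wrap(arma::vec(dbeta)));
    if (wantDx) {
      dxprev.attr("dim") = dims[st];
      dcur = dxprev;
    }
  }
  List out = List::create(_["grads"] = grads);
  if (needDx) out["dx"] = dcur;
  return out;
}
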