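// Hot layer primitives for the feature-extraction CNN.
//
// Activations are C x (P*B) matrices, block-major: the columns of sample b
// occupy [b*P, (b+1)*P). Convolutions are stride-1 "same"; each block is
// lowered to a (C*d) x P im2col buffer and multiplied in one dgemm, which
// keeps both the copies and the FLOPs in tight BLAS-friendly shapes.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
using namespace Rcpp;

// Reorganize an F x C x d filter cube into an F x (C*d) matrix whose
// column block t holds the t-th tap, matching the im2col row layout.
static arma::mat flatten_filters(const NumericVector& W) {
  IntegerVector wd = W.attr("dim");
  int F = wd[0], C = wd[1], d = wd[2];
  arma::mat Wmat(F, (size_t)C * d);
  const double* wp = W.begin();
  for (int t = 0; t < d; ++t)
    for (int c = 0; c < C; ++c)
      for (int f = 0; f < F; ++f)
        Wmat(f, (size_t)t * C + c) = wp[f + (size_t)F * (c + (size_t)C * t)];
  return Wmat;
}

// im2col for one block: col is (C*d) x P, zero-padded at the borders.
static void fill_col(arma::mat& col, const arma::mat& Xv,
                     size_t block_off, int C, int d, int P, int pad_l) {
  col.zeros();
  for (int t = 0; t < d; ++t) {
    int p_start = std::max(0, pad_l - t);
    int p_end = std::min(P, P + pad_l - t);  // exclusive
    if (p_end <= p_start) continue;
    int shift = t - pad_l;
    col.submat((size_t)t * C, p_start, (size_t)t * C + C - 1, p_end - 1) =
        Xv.cols(block_off + p_start + shift, block_off + p_end - 1 + shift);
  }
}

// [[Rcpp::export]]
NumericMatrix conv_fwd_cpp(NumericVector W, NumericVector b,
                           NumericMatrix X, int P, int B) {
  IntegerVector wd = W.attr("dim");
  int F = wd[0], C = wd[1], d = wd[2];
  int pad_l = (d - 1) / 2;
  arma::mat Xv(X.begin(), C, (size_t)P * B, false, true);
  arma::mat Wmat = flatten_filters(W);
  arma::vec bv(b.begin(), F, false, true);
  NumericMatrix out(F, P * B);
  arma::mat outv(out.begin(), F, (size_t)P * B, false, true);
  arma::mat col((size_t)C * d, P);
  for (int bb = 0; bb < B; ++bb) {
    size_t off = (size_t)bb * P;
    fill_col(col, Xv, off, C, d, P, pad_l);
    outv.cols(off, off + P - 1) = Wmat * col;
  }
  outv.each_col() += bv;
  return out;
}

// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector W, NumericMatrix dOut,
                  NumericMatrix X, int P, int B) {
  IntegerVector wd = W.attr("dim");
  int F = wd[0], C = wd[1], d = wd[2];
  int pad_l = (d - 1) / 2;
  arma::mat Xv(X.begin(), C, (size_t)P * B, false, true);
  arma::mat dOv(dOut.begin(), F, (size_t)P * B, false, true);
  arma::mat Wmat = flatten_filters(W);
  arma::mat dWmat(F, (size_t)C * d, arma::fill::zeros);
  NumericMatrix dX(C, P * B);
  arma::mat dXv(dX.begin(), C, (size_t)P * B, false, true);
  arma::mat col((size_t)C * d, P);
  for (int bb = 0; bb < B; ++bb) {
    size_t off = (size_t)bb * P;
    fill_col(col, Xv, off, C, d, P, pad_l);
    const arma::mat dOb = dOv.cols(off, off + P - 1);
    dWmat += dOb * col.t();
    arma::mat dcol = Wmat.t() * dOb;  // (C*d) x P
    for (int t = 0; t < d; ++t) {
      int p_start = std::max(0, pad_l - t);
      int p_end = std::min(P, P + pad_l - t);
      if (p_end <= p_start) continue;
      int shift = t - pad_l;
      dXv.cols(off + p_start + shift, off + p_end - 1 + shift) +=
          dcol.submat((size_t)t * C, p_start, (size_t)t * C + C - 1, p_end - 1);
    }
  }
  NumericVector dW(F * C * d);
  dW.attr("dim") = IntegerVector::create(F, C, d);
  double* dwp = dW.begin();
  for (int t = 0; t < d; ++t)
    for (int c = 0; c < C; ++c)
      for (int f = 0; f < F; ++f)
        dwp[f + (size_t)F * (c + (size_t)C * t)] = dWmat(f, (size_t)t * C + c);
  NumericVector db(F);
  arma::vec dbv(db.begin(), F, false, true);
  dbv = arma::sum(dOv, 1);
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// Fused batch norm + ReLU. Training mode computes batch statistics over all
// positions and samples of each filter; inference mode uses running stats.
// [[Rcpp::export]]
List bn_relu_fwd_cpp(NumericMatrix Z, NumericVector gamma, NumericVector beta,
                     NumericVector run_mean, NumericVector run_var,
                     double eps, bool training) {
  int F = Z.nrow();
  size_t N = Z.ncol();
  arma::mat Zv(Z.begin(), F, N, false, true);
  NumericMatrix out(F, N);
  arma::mat outv(out.begin(), F, N, false, true);
  const double* zp = Z.begin();
  double* op = out.begin();
  const double* gp = gamma.begin();
  const double* bp = beta.begin();
  if (training) {
    std::vector<double> sum(F, 0.0), sumsq(F, 0.0);
    for (size_t j = 0; j < N; ++j) {
      const double* zc = zp + j * F;
      for (int f = 0; f < F; ++f) {
        sum[f] += zc[f];
        sumsq[f] += zc[f] * zc[f];
      }
    }
    NumericVector mu(F), v(F), isd(F);
    for (int f = 0; f < F; ++f) {
      mu[f] = sum[f] / N;
      v[f] = sumsq[f] / N - mu[f] * mu[f];
      if (v[f] < 0) v[f] = 0;
      isd[f] = 1.0 / std::sqrt(v[f] + eps);
    }
    NumericMatrix xhat(F, N);
    double* xp = xhat.begin();
    const double* mup = mu.begin();
    const double* ip = isd.begin();
    for (size_t j = 0; j < N; ++j) {
      const double* zc = zp + j * F;
      double* xc = xp + j * F;
      double* oc = op + j * F;
      for (int f = 0; f < F; ++f) {
        double xh = (zc[f] - mup[f]) * ip[f];
        xc[f] = xh;
        double y = gp[f] * xh + bp[f];
        oc[f] = y > 0 ? y : 0.0;
      }
    }
    return List::create(_["out"] = out, _["xhat"] = xhat, _["isd"] = isd,
                        _["mu"] = mu, _["v"] = v);
  }
  std::vector<double> isd(F), rm(F);
  for (int f = 0; f < F; ++f) {
    isd[f] = 1.0 / std::sqrt(run_var[f] + eps);
    rm[f] = run_mean[f];
  }
  for (size_t j = 0; j < N; ++j) {
    const double* zc = zp + j * F;
    double* oc = op + j * F;
    for (int f = 0; f < F; ++f) {
      double y = gp[f] * (zc[f] - rm[f]) * isd[f] + bp[f];
      oc[f] = y > 0 ? y : 0.0;
    }
  }
  return List::create(_["out"] = out);
}

// Backward through ReLU then batch norm. dR is the gradient w.r.t. the
// post-ReLU output; y is that output (used as the ReLU mask).
// [[Rcpp::export]]
List bn_relu_bwd_cpp(NumericMatrix dR, NumericMatrix y, NumericMatrix xhat,
                     NumericVector isd, NumericVector gamma) {
  int F = dR.nrow();
  size_t N = dR.ncol();
  const double* drp = dR.begin();
  const double* yp = y.begin();
  const double* xp = xhat.begin();
  NumericVector dgamma(F), dbeta(F);
  double* dgp = dgamma.begin();
  double* dbp = dbeta.begin();
  // pass 1: masked gradient sums
  for (size_t j = 0; j < N; ++j) {
    const double* drc = drp + j * F;
    const double* yc = yp + j * F;
    const double* xc = xp + j * F;
    for (int f = 0; f < F; ++f) {
      if (yc[f] > 0) {
        dbp[f] += drc[f];
        dgp[f] += drc[f] * xc[f];
      }
    }
  }
  NumericMatrix dZ(F, N);
  double* dzp = dZ.begin();
  std::vector<double> mean_dy(F), mean_dyxh(F), gi(F);
  for (int f = 0; f < F; ++f) {
    mean_dy[f] = dbp[f] / (double)N;
    mean_dyxh[f] = dgp[f] / (double)N;
    gi[f] = gamma[f] * isd[f];
  }
  for (size_t j = 0; j < N; ++j) {
    const double* drc = drp + j * F;
    const double* yc = yp + j * F;
    const double* xc = xp + j * F;
    double* dzc = dzp + j * F;
    for (int f = 0; f < F; ++f) {
      double dy = yc[f] > 0 ? drc[f] : 0.0;
      dzc[f] = gi[f] * (dy - mean_dy[f] - xc[f] * mean_dyxh[f]);
    }
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Max pooling with width/stride s; the earliest position wins ties.
// [[Rcpp::export]]
List pool_fwd_cpp(NumericMatrix X, int P, int B, int s) {
  int F = X.nrow();
  int Pout = P / s;
  arma::mat Xv(X.begin(), F, (size_t)P * B, false, true);
  NumericMatrix out(F, Pout * B);
  IntegerMatrix choice(F, Pout * B);
  arma::mat outv(out.begin(), F, (size_t)Pout * B, false, true);
  for (int bb = 0; bb < B; ++bb)
    for (int p = 0; p < Pout; ++p) {
      size_t incol0 = (size_t)bb * P + (size_t)p * s;
      size_t outcol = (size_t)bb * Pout + p;
      for (int f = 0; f < F; ++f) {
        double best = Xv(f, incol0);
        int bj = 0;
        for (int j = 1; j < s; ++j) {
          double v = Xv(f, incol0 + j);
          if (v > best) { best = v; bj = j; }
        }
        outv(f, outcol) = best;
        choice(f, outcol) = bj;
      }
    }
  return List::create(_["out"] = out, _["choice"] = choice);
}

// [[Rcpp::export]]
NumericMatrix pool_bwd_cpp(NumericMatrix dOut, IntegerMatrix choice,
                           int P, int B, int s) {
  int F = dOut.nrow();
  int Pout = P / s;
  NumericMatrix dX(F, P * B);
  for (int bb = 0; bb < B; ++bb)
    for (int p = 0; p < Pout; ++p) {
      size_t incol0 = (size_t)bb * P + (size_t)p * s;
      size_t outcol = (size_t)bb * Pout + p;
      for (int f = 0; f < F; ++f)
        dX(f, incol0 + choice(f, outcol)) = dOut(f, outcol);
    }
  return dX;
}
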