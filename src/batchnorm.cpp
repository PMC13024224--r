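// Per-channel batch normalisation over (B, C, T, H, W) arrays, avoiding
// the axis permutations an R implementation needs. For channel c the
// elements sit at offset b + B*c + B*C*m (m over T*H*W), so the inner
// loops run over contiguous stretches of B values.

#include <Rcpp.h>
using namespace Rcpp;

namespace {
struct BnDims {
  R_xlen_t B, C, M;  // M = T*H*W
};

BnDims bn_dims(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 5) stop("input must be a 5-axis array");
  return BnDims{(R_xlen_t)d[0], (R_xlen_t)d[1],
                (R_xlen_t)d[2] * d[3] * d[4]};
}
}  // namespace

// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar, bool train,
                double momentum, double eps) {
  BnDims d = bn_dims(x);
  const R_xlen_t n = d.B * d.M;
  NumericVector mu(d.C), var(d.C);
  if (train) {
    for (R_xlen_t c = 0; c < d.C; ++c) {
      double s = 0, s2 = 0;
      const double* base = REAL(x) + d.B * c;
      for (R_xlen_t m = 0; m < d.M; ++m) {
        const double* p = base + d.B * d.C * m;
        for (R_xlen_t b = 0; b < d.B; ++b) { s += p[b]; s2 += p[b] * p[b]; }
      }
      mu[c] = s / n;
      var[c] = s2 / n - mu[c] * mu[c];
    }
  } else {
    mu = clone(rmean);
    var = clone(rvar);
  }
  NumericVector new_rmean = clone(rmean), new_rvar = clone(rvar);
  if (train) {
    for (R_xlen_t c = 0; c < d.C; ++c) {
      new_rmean[c] = (1 - momentum) * rmean[c] + momentum * mu[c];
      new_rvar[c] = (1 - momentum) * rvar[c] + momentum * var[c];
    }
  }
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  NumericVector invstd(d.C);
  for (R_xlen_t c = 0; c < d.C; ++c) {
    invstd[c] = 1.0 / std::sqrt(var[c] + eps);
    const double a = gamma[c] * invstd[c];
    const double bshift = beta[c] - a * mu[c];
    const double* px = REAL(x) + d.B * c;
    double* py = REAL(y) + d.B * c;
    for (R_xlen_t m = 0; m < d.M; ++m) {
      const double* p = px + d.B * d.C * m;
      double* q = py + d.B * d.C * m;
      for (R_xlen_t b = 0; b < d.B; ++b) q[b] = a * p[b] + bshift;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["invstd"] = invstd,
                      _["rmean"] = new_rmean, _["rvar"] = new_rvar);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mu, NumericVector invstd) {
  BnDims d = bn_dims(x);
  const R_xlen_t n = d.B * d.M;
  NumericVector dgamma(d.C), dbeta(d.C);
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  for (R_xlen_t c = 0; c < d.C; ++c) {
    const double* px = REAL(x) + d.B * c;
    const double* pdy = REAL(dy) + d.B * c;
    double sg = 0, sb = 0;
    for (R_xlen_t m = 0; m < d.M; ++m) {
      const double* xp = px + d.B * d.C * m;
      const double* gp = pdy + d.B * d.C * m;
      for (R_xlen_t b = 0; b < d.B; ++b) {
        const double xhat = (xp[b] - mu[c]) * invstd[c];
        sg += gp[b] * xhat;
        sb += gp[b];
      }
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    // dx = (gamma*invstd) * (dy - mean(dy) - xhat * mean(dy*xhat))
    const double a = gamma[c] * invstd[c];
    const double mean_dy = sb / n;
    const double mean_dyx = sg / n;
    double* pdx = REAL(dx) + d.B * c;
    for (R_xlen_t m = 0; m < d.M; ++m) {
      const double* xp = px + d.B * d.C * m;
      const double* gp = pdy + d.B * d.C * m;
      double* op = pdx + d.B * d.C * m;
      for (R_xlen_t b = 0; b < d.B; ++b) {
        const double xhat = (xp[b] - mu[c]) * invstd[c];
        op[b] = a * (gp[b] - mean_dy - xhat * mean_dyx);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector relu_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* px = REAL(x);
  double* py = REAL(y);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) py[i] = px[i] > 0 ? px[i] : 0.0;
  return y;
}
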