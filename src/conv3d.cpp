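// 3D convolution kernels for the video backbone.
//
// Tensor layout follows the R arrays used throughout the package:
//   activations  dim = (B, C, T, H, W)   (column-major, B fastest)
//   weights      dim = (Cout, Cin, kt, kh, kw)
//
// Convolution is implemented as im2col + BLAS gemm (via Armadillo). The
// column matrix is stored N x K (N = B*To*Ho*Wo output positions, K =
// Cin*kt*kh*kw taps) so that the batch index is innermost and every
// gather/scatter runs over contiguous memory in both the activations and
// the column matrix. The backward pass reuses im2col for the weight
// gradient and scatters dY * W back through col2im for the input gradient.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Dims5 {
  int d0, d1, d2, d3, d4;
};

Dims5 get_dims(const NumericVector& x, const char* what) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 5) stop("%s must be a 5-axis array", what);
  return Dims5{d[0], d[1], d[2], d[3], d[4]};
}

inline int out_size(int s, int k, int stride, int pad) {
  return (s + 2 * pad - k) / stride + 1;
}

// N x K column matrix; row n = b + B*(to + To*(ho + Ho*wo)),
// col k = c + Cin*(dt + kt*(dh + kh*dw)).
void fill_im2col(arma::mat& col, const double* x, const Dims5& xd,
                 int kt, int kh, int kw,
                 int st, int sh, int sw,
                 int pt, int ph, int pw,
                 int To, int Ho, int Wo) {
  const int B = xd.d0, Cin = xd.d1, T = xd.d2, H = xd.d3, W = xd.d4;
  // every element is either copied or zero-filled below; no global memset

  for (int dw = 0; dw < kw; ++dw) {
    for (int dh = 0; dh < kh; ++dh) {
      for (int dt = 0; dt < kt; ++dt) {
        for (int c = 0; c < Cin; ++c) {
          const int k = c + Cin * (dt + kt * (dh + kh * dw));
          double* cptr = col.colptr(k);
          for (int wo = 0; wo < Wo; ++wo) {
            const int w0 = wo * sw - pw + dw;
            double* wbase = cptr + (arma::uword)B * (arma::uword)To * Ho * wo;
            if (w0 < 0 || w0 >= W) {
              std::fill(wbase, wbase + (arma::uword)B * To * Ho, 0.0);
              continue;
            }
            for (int ho = 0; ho < Ho; ++ho) {
              const int h0 = ho * sh - ph + dh;
              double* hbase = wbase + (arma::uword)B * To * ho;
              if (h0 < 0 || h0 >= H) {
                std::fill(hbase, hbase + (arma::uword)B * To, 0.0);
                continue;
              }
              for (int to = 0; to < To; ++to) {
                const int t0 = to * st - pt + dt;
                double* dst = hbase + (arma::uword)B * to;
                if (t0 < 0 || t0 >= T) {
                  std::fill(dst, dst + B, 0.0);
                  continue;
                }
                const double* src = x + (arma::uword)B *
                  (c + (arma::uword)Cin * (t0 + (arma::uword)T * (h0 + (arma::uword)H * w0)));
                std::copy(src, src + B, dst);
              }
            }
          }
        }
      }
    }
  }
}

// scatter-add the N x K matrix back into the (B, Cin, T, H, W) array
void col2im(const arma::mat& col, double* dx, const Dims5& xd,
            int kt, int kh, int kw,
            int st, int sh, int sw,
            int pt, int ph, int pw,
            int To, int Ho, int Wo) {
  const int B = xd.d0, Cin = xd.d1, T = xd.d2, H = xd.d3, W = xd.d4;
  for (int dw = 0; dw < kw; ++dw) {
    for (int dh = 0; dh < kh; ++dh) {
      for (int dt = 0; dt < kt; ++dt) {
        for (int c = 0; c < Cin; ++c) {
          const int k = c + Cin * (dt + kt * (dh + kh * dw));
          const double* cptr = col.colptr(k);
          for (int wo = 0; wo < Wo; ++wo) {
            const int w0 = wo * sw - pw + dw;
            if (w0 < 0 || w0 >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              const int h0 = ho * sh - ph + dh;
              if (h0 < 0 || h0 >= H) continue;
              for (int to = 0; to < To; ++to) {
                const int t0 = to * st - pt + dt;
                if (t0 < 0 || t0 >= T) continue;
                double* dst = dx + (arma::uword)B *
                  (c + (arma::uword)Cin * (t0 + (arma::uword)T * (h0 + (arma::uword)H * w0)));
                const double* src = cptr + (arma::uword)B *
                  (to + (arma::uword)To * (ho + (arma::uword)Ho * wo));
                for (int b = 0; b < B; ++b) dst[b] += src[b];
              }
            }
          }
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
SEXP conv3d_fwd_cpp(NumericVector x, NumericVector w, NumericVector bias,
                    IntegerVector stride, IntegerVector pad,
                    bool want_col = false) {
  Dims5 xd = get_dims(x, "input");
  Dims5 wd = get_dims(w, "weights");
  const int B = xd.d0, Cin = xd.d1, T = xd.d2, H = xd.d3, W = xd.d4;
  const int Cout = wd.d0, kt = wd.d2, kh = wd.d3, kw = wd.d4;
  if (wd.d1 != Cin) stop("weight input channels (%d) do not match input (%d)", wd.d1, Cin);
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = out_size(T, kt, st, pt);
  const int Ho = out_size(H, kh, sh, ph);
  const int Wo = out_size(W, kw, sw, pw);
  if (To < 1 || Ho < 1 || Wo < 1) stop("convolution output would be empty");

  const int K = Cin * kt * kh * kw;
  const arma::uword N = (arma::uword)B * To * Ho * Wo;
  // when the caller wants the column matrix back, build it in R memory so
  // no extra copy is needed
  NumericMatrix colR;
  arma::mat col;
  if (want_col) {
    colR = NumericMatrix((R_xlen_t)N, K);
    col = arma::mat(colR.begin(), N, K, false, true);
  } else {
    col.set_size(N, K);
  }
  fill_im2col(col, REAL(x), xd, kt, kh, kw, st, sh, sw, pt, ph, pw, To, Ho, Wo);
  arma::mat Wm(const_cast<double*>(REAL(w)), Cout, K, false, true);
  arma::mat Yt = col * Wm.t();  // N x Cout
  Yt.each_row() += arma::rowvec(const_cast<double*>(REAL(bias)), Cout, false, true);

  // output (B, Cout, To, Ho, Wo): index b + B*(o + Cout*m), with row
  // n = b + B*m of Yt; for fixed o both sides are contiguous in b.
  NumericVector out((R_xlen_t)B * Cout * To * Ho * Wo);
  out.attr("dim") = IntegerVector::create(B, Cout, To, Ho, Wo);
  double* optr = REAL(out);
  const arma::uword M = (arma::uword)To * Ho * Wo;
  for (int o = 0; o < Cout; ++o) {
    const double* yptr = Yt.colptr(o);
    for (arma::uword m = 0; m < M; ++m) {
      const double* src = yptr + (arma::uword)B * m;
      double* dst = optr + (arma::uword)B * (o + (arma::uword)Cout * m);
      std::copy(src, src + B, dst);
    }
  }
  if (!want_col) return out;
  return List::create(_["y"] = out, _["col"] = colR);
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    IntegerVector stride, IntegerVector pad,
                    Nullable<NumericMatrix> col_cache = R_NilValue) {
  Dims5 xd = get_dims(x, "input");
  Dims5 wd = get_dims(w, "weights");
  Dims5 yd = get_dims(dy, "output gradient");
  const int B = xd.d0, Cin = xd.d1, T = xd.d2, H = xd.d3, W = xd.d4;
  const int Cout = wd.d0, kt = wd.d2, kh = wd.d3, kw = wd.d4;
  const int st = stride[0], sh = stride[1], sw = stride[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int To = yd.d2, Ho = yd.d3, Wo = yd.d4;
  if (yd.d0 != B || yd.d1 != Cout) stop("gradient dims do not match");

  const int K = Cin * kt * kh * kw;
  const arma::uword N = (arma::uword)B * To * Ho * Wo;
  const arma::uword M = (arma::uword)To * Ho * Wo;

  // gather dY into N x Cout
  arma::mat dYt(N, Cout);
  const double* gptr = REAL(dy);
  for (int o = 0; o < Cout; ++o) {
    double* dst0 = dYt.colptr(o);
    for (arma::uword m = 0; m < M; ++m) {
      const double* src = gptr + (arma::uword)B * (o + (arma::uword)Cout * m);
      std::copy(src, src + B, dst0 + (arma::uword)B * m);
    }
  }

  arma::mat col;
  if (col_cache.isNotNull()) {
    NumericMatrix cm(col_cache);
    col = arma::mat(cm.begin(), N, K, false, true);
  } else {
    col.set_size(N, K);
    fill_im2col(col, REAL(x), xd, kt, kh, kw, st, sh, sw, pt, ph, pw, To, Ho, Wo);
  }
  arma::mat Wm(const_cast<double*>(REAL(w)), Cout, K, false, true);

  arma::mat dWt = col.t() * dYt;            // K x Cout
  arma::rowvec db = arma::sum(dYt, 0);      // Cout
  arma::mat dcol = dYt * Wm;                // N x K

  NumericVector dx((R_xlen_t)B * Cin * T * H * W);
  dx.attr("dim") = IntegerVector::create(B, Cin, T, H, W);
  col2im(dcol, REAL(dx), xd, kt, kh, kw, st, sh, sw, pt, ph, pw, To, Ho, Wo);

  arma::mat dW = dWt.t();                   // Cout x K, matches weight layout
  NumericVector dwv(dW.memptr(), dW.memptr() + (R_xlen_t)Cout * K);
  dwv.attr("dim") = IntegerVector::create(Cout, Cin, kt, kh, kw);
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
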