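// Dense convolution / pooling kernels for the two scoring branches.
// Tensor layout matches the R side: column-major [channels, height,
// width, batch]. "same" padding pads (k-1)/2 on the leading edge and the
// remainder on the trailing edge, mirroring the R reference semantics.

#include <Rcpp.h>
using namespace Rcpp;

// im2col: unfold kh x kw patches into a [cin*kh*kw, ho*wo*nb] matrix so
// the convolution itself becomes one BLAS product on the R side.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int kh, int kw, bool same) {
  IntegerVector dx = x.attr("dim");
  const int cin = dx[0], h = dx[1], w = dx[2], nb = dx[3];
  const int pt = same ? (kh - 1) / 2 : 0;
  const int pl = same ? (kw - 1) / 2 : 0;
  const int ho = same ? h : h - kh + 1;
  const int wo = same ? w : w - kw + 1;
  const R_xlen_t n = static_cast<R_xlen_t>(ho) * wo * nb;
  NumericMatrix col(cin * kh * kw, n);
  const double *xp = x.begin();
  double *cp = col.begin();
  const int crows = cin * kh * kw;
  R_xlen_t pos = 0;
  for (int ib = 0; ib < nb; ib++) {
    for (int ow = 0; ow < wo; ow++) {
      for (int oh = 0; oh < ho; oh++, pos++) {
        double *co = cp + static_cast<R_xlen_t>(crows) * pos;
        for (int dwi = 0; dwi < kw; dwi++) {
          const int iw = ow + dwi - pl;
          for (int dh = 0; dh < kh; dh++) {
            const int ih = oh + dh - pt;
            double *dst = co + cin * (dh + kh * dwi);
            if (iw < 0 || iw >= w || ih < 0 || ih >= h) {
              for (int ci = 0; ci < cin; ci++) dst[ci] = 0.0;
            } else {
              const double *src = xp + static_cast<R_xlen_t>(cin) *
                (ih + static_cast<R_xlen_t>(h) *
                 (iw + static_cast<R_xlen_t>(w) * ib));
              for (int ci = 0; ci < cin; ci++) dst[ci] = src[ci];
            }
          }
        }
      }
    }
  }
  return col;
}

// scatter-add the column gradient back onto the input tensor
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dcol, IntegerVector in_dim,
                         int kh, int kw, bool same) {
  const int cin = in_dim[0], h = in_dim[1], w = in_dim[2], nb = in_dim[3];
  const int pt = same ? (kh - 1) / 2 : 0;
  const int pl = same ? (kw - 1) / 2 : 0;
  const int ho = same ? h : h - kh + 1;
  const int wo = same ? w : w - kw + 1;
  NumericVector dx(static_cast<R_xlen_t>(cin) * h * w * nb);
  dx.attr("dim") = in_dim;
  double *dxp = dx.begin();
  const double *cp = dcol.begin();
  const int crows = cin * kh * kw;
  R_xlen_t pos = 0;
  for (int ib = 0; ib < nb; ib++) {
    for (int ow = 0; ow < wo; ow++) {
      for (int oh = 0; oh < ho; oh++, pos++) {
        const double *co = cp + static_cast<R_xlen_t>(crows) * pos;
        for (int dwi = 0; dwi < kw; dwi++) {
          const int iw = ow + dwi - pl;
          if (iw < 0 || iw >= w) continue;
          for (int dh = 0; dh < kh; dh++) {
            const int ih = oh + dh - pt;
            if (ih < 0 || ih >= h) continue;
            const double *src = co + cin * (dh + kh * dwi);
            double *dst = dxp + static_cast<R_xlen_t>(cin) *
              (ih + static_cast<R_xlen_t>(h) *
               (iw + static_cast<R_xlen_t>(w) * ib));
            for (int ci = 0; ci < cin; ci++) dst[ci] += src[ci];
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector avgpool_fwd_cpp(NumericVector x, int ph, int pw) {
  IntegerVector d = x.attr("dim");
  const int c = d[0], h = d[1], w = d[2], nb = d[3];
  const int ho = h / ph, wo = w / pw;
  NumericVector y(static_cast<R_xlen_t>(c) * ho * wo * nb);
  y.attr("dim") = IntegerVector::create(c, ho, wo, nb);
  const double scale = 1.0 / (ph * pw);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int ib = 0; ib < nb; ib++)
    for (int ow = 0; ow < wo; ow++)
      for (int oh = 0; oh < ho; oh++) {
        double *yo = yp + static_cast<R_xlen_t>(c) *
          (oh + static_cast<R_xlen_t>(ho) * (ow + static_cast<R_xlen_t>(wo) * ib));
        for (int j = 0; j < pw; j++)
          for (int i = 0; i < ph; i++) {
            const double *xs = xp + static_cast<R_xlen_t>(c) *
              ((oh * ph + i) + static_cast<R_xlen_t>(h) *
               ((ow * pw + j) + static_cast<R_xlen_t>(w) * ib));
            for (int ci = 0; ci < c; ci++) yo[ci] += xs[ci] * scale;
          }
      }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool_bwd_cpp(NumericVector dy, IntegerVector in_dim,
                              int ph, int pw) {
  const int c = in_dim[0], h = in_dim[1], w = in_dim[2], nb = in_dim[3];
  IntegerVector d = dy.attr("dim");
  const int ho = d[1], wo = d[2];
  NumericVector dx(static_cast<R_xlen_t>(c) * h * w * nb);
  dx.attr("dim") = in_dim;
  const double scale = 1.0 / (ph * pw);
  const double *dyp = dy.begin();
  double *dxp = dx.begin();
  for (int ib = 0; ib < nb; ib++)
    for (int ow = 0; ow < wo; ow++)
      for (int oh = 0; oh < ho; oh++) {
        const double *dyo = dyp + static_cast<R_xlen_t>(c) *
          (oh + static_cast<R_xlen_t>(ho) * (ow + static_cast<R_xlen_t>(wo) * ib));
        for (int j = 0; j < pw; j++)
          for (int i = 0; i < ph; i++) {
            double *xs = dxp + static_cast<R_xlen_t>(c) *
              ((oh * ph + i) + static_cast<R_xlen_t>(h) *
               ((ow * pw + j) + static_cast<R_xlen_t>(w) * ib));
            for (int ci = 0; ci < c; ci++) xs[ci] += dyo[ci] * scale;
          }
      }
  return dx;
}

// fused elementwise helpers (single pass, no intermediate allocations)

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector d, NumericVector pre) {
  NumericVector out(d.size());
  out.attr("dim") = d.attr("dim");
  const double *dp = d.begin(), *pp = pre.begin();
  double *op = out.begin();
  const R_xlen_t n = d.size();
  for (R_xlen_t i = 0; i < n; i++) op[i] = pp[i] > 0.0 ? dp[i] : 0.0;
  return out;
}

// [[Rcpp::export]]
NumericVector sigmoid_cpp(NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double *xp = x.begin();
  double *op = out.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; i++) op[i] = 1.0 / (1.0 + std::exp(-xp[i]));
  return out;
}

// [[Rcpp::export]]
NumericVector sigmoid_bwd_cpp(NumericVector d, NumericVector s) {
  NumericVector out(d.size());
  out.attr("dim") = d.attr("dim");
  const double *dp = d.begin(), *sp = s.begin();
  double *op = out.begin();
  const R_xlen_t n = d.size();
  for (R_xlen_t i = 0; i < n; i++) op[i] = dp[i] * sp[i] * (1.0 - sp[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector relu_cpp(NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double *xp = x.begin();
  double *op = out.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; i++) op[i] = xp[i] > 0.0 ? xp[i] : 0.0;
  return out;
}
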