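// Hot inner loops of the convolutional network: im2col / col2im and 2x2
// max pooling. Matrix products themselves go through R's BLAS; these
// routines only rearrange data, which dominates run time if done with R
// subscripting. Layout is channel-first: X[c, h, w, n].

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& X, int C, int H, int W, int N,
                         int KH, int KW) {
  const int OH = H - KH + 1, OW = W - KW + 1;
  const int CKK = C * KH * KW;
  NumericMatrix cols(CKK, OH * OW * N);
  const double* x = X.begin();
  double* out = cols.begin();
  for (int j = 0; j < KW; ++j) {
    for (int i = 0; i < KH; ++i) {
      const int rowbase = C * (i + KH * j);
      for (int n = 0; n < N; ++n) {
        for (int ow = 0; ow < OW; ++ow) {
          const double* src = x + C * ((i) + H * ((j + ow) + W * n));
          double* dst = out + rowbase + (R_xlen_t)CKK * (OH * (ow + OW * n));
          for (int oh = 0; oh < OH; ++oh) {
            std::copy(src, src + C, dst);
            src += C;
            dst += CKK;
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& cols, int C, int H, int W,
                         int N, int KH, int KW) {
  const int OH = H - KH + 1, OW = W - KW + 1;
  const int CKK = C * KH * KW;
  NumericVector X((R_xlen_t)C * H * W * N);
  double* x = X.begin();
  const double* in = cols.begin();
  for (int j = 0; j < KW; ++j) {
    for (int i = 0; i < KH; ++i) {
      const int rowbase = C * (i + KH * j);
      for (int n = 0; n < N; ++n) {
        for (int ow = 0; ow < OW; ++ow) {
          double* dst = x + C * ((i) + H * ((j + ow) + W * n));
          const double* src = in + rowbase + (R_xlen_t)CKK * (OH * (ow + OW * n));
          for (int oh = 0; oh < OH; ++oh) {
            for (int c = 0; c < C; ++c) dst[c] += src[c];
            src += CKK;
            dst += C;
          }
        }
      }
    }
  }
  X.attr("dim") = IntegerVector::create(C, H, W, N);
  return X;
}

// 2x2 non-overlapping max pooling; ties go to the first element in
// (top-left, bottom-left, top-right, bottom-right) scan order.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericVector& X, int C, int H, int W, int N) {
  const int OH = H / 2, OW = W / 2;
  NumericVector out((R_xlen_t)C * OH * OW * N);
  IntegerVector which((R_xlen_t)C * OH * OW * N);
  const double* x = X.begin();
  double* o = out.begin();
  int* wh = which.begin();
  R_xlen_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const R_xlen_t base = (R_xlen_t)C * (2 * oh + H * (2 * ow + W * n));
        const R_xlen_t offs[4] = {0, (R_xlen_t)C, (R_xlen_t)C * H,
                                  (R_xlen_t)C * H + C};
        for (int c = 0; c < C; ++c, ++q) {
          double best = x[base + c];
          int bi = 0;
          for (int k = 1; k < 4; ++k) {
            const double v = x[base + offs[k] + c];
            if (v > best) { best = v; bi = k; }
          }
          o[q] = best;
          wh[q] = bi;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, OH, OW, N);
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(const NumericVector& dOut,
                              const IntegerVector& which, int C, int H,
                              int W, int N) {
  const int OH = H / 2, OW = W / 2;
  NumericVector dX((R_xlen_t)C * H * W * N);
  double* dx = dX.begin();
  const double* dout = dOut.begin();
  const int* wh = which.begin();
  R_xlen_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const R_xlen_t base = (R_xlen_t)C * (2 * oh + H * (2 * ow + W * n));
        const R_xlen_t offs[4] = {0, (R_xlen_t)C, (R_xlen_t)C * H,
                                  (R_xlen_t)C * H + C};
        for (int c = 0; c < C; ++c, ++q) {
          dx[base + offs[wh[q]] + c] += dout[q];
        }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(C, H, W, N);
  return dX;
}
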