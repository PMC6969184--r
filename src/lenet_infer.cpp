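// Fused inference path for the LeNet-variant classifier. Training keeps
// the modular R forward/backward (gradients, dropout, caches); scoring a
// continuous stream only needs the forward pass, which this routine runs
// with preallocated buffers and BLAS dgemm so sliding-window detection
// over hours of audio stays fast.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

namespace {

// im2col for channel-first (C,H,W,n) into a (C*K*K, OH*OW*n) buffer.
void im2col(const double* x, int C, int H, int W, int n, int K, double* out) {
  const int OH = H - K + 1, OW = W - K + 1;
  const int CKK = C * K * K;
  for (int j = 0; j < K; ++j) {
    for (int i = 0; i < K; ++i) {
      const int rowbase = C * (i + K * j);
      for (int b = 0; b < n; ++b) {
        for (int ow = 0; ow < OW; ++ow) {
          const double* src = x + (R_xlen_t)C * (i + H * ((j + ow) + W * b));
          double* dst = out + rowbase + (R_xlen_t)CKK * (OH * (ow + OW * b));
          for (int oh = 0; oh < OH; ++oh) {
            std::copy(src, src + C, dst);
            src += C;
            dst += CKK;
          }
        }
      }
    }
  }
}

// C := tanh(A^T B + bias), A (K x M), B (K x N), C (M x N)
void gemm_tanh(const double* A, const double* B, int K, int M, int N,
               const double* bias, double* C) {
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("T", "N", &M, &N, &K, &one, A, &K, B, &K, &zero, C, &M
                  FCONE FCONE);
  for (R_xlen_t q = 0; q < (R_xlen_t)M * N; ++q) {
    C[q] = std::tanh(C[q] + bias[q % M]);
  }
}

// 2x2 max pool, (C,H,W,n) -> (C,H/2,W/2,n)
void pool2(const double* x, int C, int H, int W, int n, double* out) {
  const int OH = H / 2, OW = W / 2;
  R_xlen_t q = 0;
  for (int b = 0; b < n; ++b) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double* base = x + (R_xlen_t)C * (2 * oh + H * (2 * ow + W * b));
        const double* r2 = base + C;
        const double* c2 = base + (R_xlen_t)C * H;
        const double* rc = c2 + C;
        for (int c = 0; c < C; ++c, ++q) {
          out[q] = std::max(std::max(base[c], r2[c]), std::max(c2[c], rc[c]));
        }
      }
    }
  }
}

}  // namespace

// Upcall-class probabilities for a (1,40,40,N) input under the
// lenet_variant weights (tanh activation). Equals the modular R forward
// pass in inference mode to numerical precision.
// [[Rcpp::export]]
NumericVector cpp_lenet_infer(const NumericVector& X, int N,
                              const NumericMatrix& W1, const NumericVector& b1,
                              const NumericMatrix& W2, const NumericVector& b2,
                              const NumericMatrix& W3, const NumericVector& b3,
                              const NumericMatrix& W4, const NumericVector& b4) {
  const int CHUNK = 64;
  NumericVector out(N);
  const int F1 = W1.ncol(), F2 = W2.ncol(), FC1 = W3.nrow();
  // geometry: 40 -> conv5 -> 36 -> pool -> 18 -> conv5 -> 14 -> pool -> 7
  std::vector<double> cols1((R_xlen_t)25 * 36 * 36 * CHUNK);
  std::vector<double> a1((R_xlen_t)F1 * 36 * 36 * CHUNK);
  std::vector<double> p1((R_xlen_t)F1 * 18 * 18 * CHUNK);
  std::vector<double> cols2((R_xlen_t)F1 * 25 * 14 * 14 * CHUNK);
  std::vector<double> a2((R_xlen_t)F2 * 14 * 14 * CHUNK);
  std::vector<double> p2((R_xlen_t)F2 * 7 * 7 * CHUNK);
  std::vector<double> h3((R_xlen_t)FC1 * CHUNK);
  std::vector<double> logits(2 * CHUNK);
  const int flat = F2 * 7 * 7;
  const double one = 1.0, zero = 0.0;
  for (int b0 = 0; b0 < N; b0 += CHUNK) {
    const int n = std::min(CHUNK, N - b0);
    const double* x = X.begin() + (R_xlen_t)1600 * b0;
    im2col(x, 1, 40, 40, n, 5, cols1.data());
    gemm_tanh(W1.begin(), cols1.data(), 25, F1, 36 * 36 * n, b1.begin(),
              a1.data());
    pool2(a1.data(), F1, 36, 36, n, p1.data());
    im2col(p1.data(), F1, 18, 18, n, 5, cols2.data());
    gemm_tanh(W2.begin(), cols2.data(), F1 * 25, F2, 14 * 14 * n, b2.begin(),
              a2.data());
    pool2(a2.data(), F2, 14, 14, n, p2.data());
    // fully connected: W3 (FC1 x flat) %*% p2 + b3, tanh
    F77_CALL(dgemm)("N", "N", &FC1, &n, &flat, &one, W3.begin(), &FC1,
                    p2.data(), &flat, &zero, h3.data(), &FC1 FCONE FCONE);
    for (R_xlen_t q = 0; q < (R_xlen_t)FC1 * n; ++q) {
      h3[q] = std::tanh(h3[q] + b3[q % FC1]);
    }
    const int two = 2;
    F77_CALL(dgemm)("N", "N", &two, &n, &FC1, &one, W4.begin(), &two,
                    h3.data(), &FC1, &zero, logits.data(), &two FCONE FCONE);
    for (int k = 0; k < n; ++k) {
      const double l1 = logits[2 * k] + b4[0], l2 = logits[2 * k + 1] + b4[1];
      const double m = std::max(l1, l2);
      const double e1 = std::exp(l1 - m), e2 = std::exp(l2 - m);
      out[b0 + k] = e2 / (e1 + e2);
    }
  }
  return out;
}
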