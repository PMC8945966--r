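// Hot kernels of the 1D-CNN: im2col convolution forward/backward and
// 2-wide max pooling. Activations are (channels, length, batch) cubes;
// convolution weights are (C_out, C_in * kernel) matrices so the heavy
// work is a single BLAS gemm per layer.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// gather the zero-padded patch matrix P (C*k, L*B) from A (C, L, B)
static arma::mat im2col(const arma::cube& A, int k, int pad) {
  const int C = A.n_rows, L = A.n_cols, B = A.n_slices;
  arma::mat P(C * k, (size_t)L * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* slab = A.slice_memptr(b);
    for (int l = 0; l < L; ++l) {
      double* col = P.colptr((size_t)b * L + l);
      for (int j = 0; j < k; ++j) {
        int pos = l + j - pad;  // source column in A
        if (pos < 0 || pos >= L) continue;
        std::memcpy(col + (size_t)j * C, slab + (size_t)pos * C,
                    C * sizeof(double));
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
List conv1d_fw_cpp(const arma::cube& A, const arma::mat& W,
                   const arma::vec& b, int k, int pad) {
  arma::mat P = im2col(A, k, pad);
  arma::mat Z = W * P;
  Z.each_col() += b;
  return List::create(_["Z"] = Z, _["P"] = P);
}

// [[Rcpp::export]]
List conv1d_bw_cpp(const arma::mat& dZ, const arma::mat& P,
                   const arma::mat& W, int C_in, int L, int B,
                   int k, int pad) {
  arma::mat dW = dZ * P.t();
  arma::vec db = arma::sum(dZ, 1);
  arma::mat dP = W.t() * dZ;  // (C_in*k, L*B)
  arma::cube dA(C_in, L, B, arma::fill::zeros);
  for (int b2 = 0; b2 < B; ++b2) {
    double* slab = dA.slice_memptr(b2);
    for (int l = 0; l < L; ++l) {
      const double* col = dP.colptr((size_t)b2 * L + l);
      for (int j = 0; j < k; ++j) {
        int pos = l + j - pad;
        if (pos < 0 || pos >= L) continue;
        double* dst = slab + (size_t)pos * C_in;
        const double* src = col + (size_t)j * C_in;
        for (int c = 0; c < C_in; ++c) dst[c] += src[c];
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dA"] = dA);
}

// ReLU then max-pool by 2 along length; returns pooled cube and the
// masks needed to route gradients back
// [[Rcpp::export]]
List relu_pool_fw_cpp(const arma::cube& Z) {
  const int C = Z.n_rows, L = Z.n_cols, B = Z.n_slices;
  const int Lh = L / 2;
  arma::cube out(C, Lh, B);
  arma::ucube takefirst(C, Lh, B);
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < Lh; ++l) {
      const double* z1 = Z.slice_memptr(b) + (size_t)(2 * l) * C;
      const double* z2 = z1 + C;
      double* o = out.slice_memptr(b) + (size_t)l * C;
      arma::uword* tf = takefirst.slice_memptr(b) + (size_t)l * C;
      for (int c = 0; c < C; ++c) {
        double a = z1[c] > 0 ? z1[c] : 0.0;
        double bb = z2[c] > 0 ? z2[c] : 0.0;
        tf[c] = a >= bb ? 1u : 0u;
        o[c] = tf[c] ? a : bb;
      }
    }
  }
  return List::create(_["out"] = out, _["takefirst"] = takefirst);
}

// [[Rcpp::export]]
arma::mat relu_pool_bw_cpp(const arma::cube& dOut, const arma::ucube& takefirst,
                           const arma::cube& Z) {
  const int C = Z.n_rows, L = Z.n_cols, B = Z.n_slices;
  const int Lh = L / 2;
  arma::mat dZ(C, (size_t)L * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < Lh; ++l) {
      const double* z1 = Z.slice_memptr(b) + (size_t)(2 * l) * C;
      const double* z2 = z1 + C;
      const double* g = dOut.slice_memptr(b) + (size_t)l * C;
      const arma::uword* tf = takefirst.slice_memptr(b) + (size_t)l * C;
      double* d1 = dZ.colptr((size_t)b * L + 2 * l);
      double* d2 = dZ.colptr((size_t)b * L + 2 * l + 1);
      for (int c = 0; c < C; ++c) {
        if (tf[c]) { if (z1[c] > 0) d1[c] = g[c]; }
        else       { if (z2[c] > 0) d2[c] = g[c]; }
      }
    }
  }
  return dZ;
}
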