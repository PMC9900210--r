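#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window helpers used by the 1D (length-axis) convolutions and the
// drug-kernel response correlation, plus a single-channel 'same' 2D
// convolution used by the spatial-attention and fusion gates.  All windows
// are centred; padding is implicit zeros.  k must be odd for the 1D ops so
// that 'same' padding is symmetric; the response correlation additionally
// supports even window heights (offset floor(k/2), matching the R side).

// Lay out the k row-windows of X (L x C) side by side: out is L x (k*C),
// out(i, (j-1)*C + c) = X(i + j - 1 - floor(k/2), c), zero outside [0, L).
// [[Rcpp::export]]
NumericMatrix cpp_im2col_len(const NumericMatrix& X, int k) {
  const int L = X.nrow(), C = X.ncol(), pad = k / 2;
  NumericMatrix out(L, k * C);
  for (int j = 0; j < k; ++j) {
    const int off = j - pad;
    const int i0 = std::max(0, -off), i1 = std::min(L, L - off);
    for (int c = 0; c < C; ++c) {
      const int oc = j * C + c;
      for (int i = i0; i < i1; ++i) out(i, oc) = X(i + off, c);
    }
  }
  return out;
}

// Adjoint of cpp_im2col_len: scatter-add D (L x k*C) back to an L x C map.
// [[Rcpp::export]]
NumericMatrix cpp_col2im_len(const NumericMatrix& D, int k, int L, int C) {
  const int pad = k / 2;
  NumericMatrix out(L, C);
  for (int j = 0; j < k; ++j) {
    const int off = j - pad;
    const int i0 = std::max(0, -off), i1 = std::min(L, L - off);
    for (int c = 0; c < C; ++c) {
      const int oc = j * C + c;
      for (int i = i0; i < i1; ++i) out(i + off, c) += D(i, oc);
    }
  }
  return out;
}

// Single-channel 'same' 2D cross-correlation of X (L x C) with W (k x k)
// plus scalar bias: gate(i,c) = b + sum_{u,v} W(u,v) X(i+u-p, c+v-p).
// [[Rcpp::export]]
NumericMatrix cpp_conv2d_same(const NumericMatrix& X, const NumericMatrix& W,
                              double bias) {
  const int L = X.nrow(), C = X.ncol(), k = W.nrow(), p = k / 2;
  NumericMatrix out(L, C);
  std::fill(out.begin(), out.end(), bias);
  for (int u = 0; u < k; ++u) {
    const int ro = u - p;
    const int i0 = std::max(0, -ro), i1 = std::min(L, L - ro);
    for (int v = 0; v < k; ++v) {
      const double w = W(u, v);
      if (w == 0.0) continue;
      const int co = v - p;
      const int c0 = std::max(0, -co), c1 = std::min(C, C - co);
      for (int c = c0; c < c1; ++c)
        for (int i = i0; i < i1; ++i) out(i, c) += w * X(i + ro, c + co);
    }
  }
  return out;
}

// Backward pass of cpp_conv2d_same: given upstream gradient G on the gate,
// return dX (L x C), dW (k x k) and db (scalar).
// [[Rcpp::export]]
List cpp_conv2d_same_bwd(const NumericMatrix& X, const NumericMatrix& W,
                         const NumericMatrix& G) {
  const int L = X.nrow(), C = X.ncol(), k = W.nrow(), p = k / 2;
  NumericMatrix dX(L, C), dW(k, k);
  double db = 0.0;
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < L; ++i) db += G(i, c);
  for (int u = 0; u < k; ++u) {
    const int ro = u - p;
    const int i0 = std::max(0, -ro), i1 = std::min(L, L - ro);
    for (int v = 0; v < k; ++v) {
      const int co = v - p;
      const int c0 = std::max(0, -co), c1 = std::min(C, C - co);
      double acc = 0.0;
      const double w = W(u, v);
      for (int c = c0; c < c1; ++c)
        for (int i = i0; i < i1; ++i) {
          const double g = G(i, c);
          acc += g * X(i + ro, c + co);
          dX(i + ro, c + co) += w * g;
        }
      dW(u, v) = acc;
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Full-channel sliding correlation of Fp (L x C) with kernel K (k x C):
// s_i = sum_{m,n} K(m,n) * Fp(i + m - floor(k/2), n), zeros outside.
// Height k may be even (the drug kernel is C_S x C_S).
// [[Rcpp::export]]
NumericVector cpp_response_vector(const NumericMatrix& Fp,
                                  const NumericMatrix& K) {
  const int L = Fp.nrow(), C = Fp.ncol(), k = K.nrow(), p = k / 2;
  if (K.ncol() != C) stop("kernel column count must match feature channels");
  NumericVector s(L);
  for (int m = 0; m < k; ++m) {
    const int off = m - p;
    const int i0 = std::max(0, -off), i1 = std::min(L, L - off);
    for (int n = 0; n < C; ++n) {
      const double w = K(m, n);
      if (w == 0.0) continue;
      for (int i = i0; i < i1; ++i) s[i] += w * Fp(i + off, n);
    }
  }
  return s;
}

// Backward of cpp_response_vector: upstream gradient g (length L) gives
// dFp(i+off, n) += g_i K(m,n) and dK(m,n) = sum_i g_i Fp(i+off, n).
// [[Rcpp::export]]
List cpp_response_vector_bwd(const NumericMatrix& Fp, const NumericMatrix& K,
                             const NumericVector& g) {
  const int L = Fp.nrow(), C = Fp.ncol(), k = K.nrow(), p = k / 2;
  NumericMatrix dFp(L, C), dK(k, C);
  for (int m = 0; m < k; ++m) {
    const int off = m - p;
    const int i0 = std::max(0, -off), i1 = std::min(L, L - off);
    for (int n = 0; n < C; ++n) {
      const double w = K(m, n);
      double acc = 0.0;
      for (int i = i0; i < i1; ++i) {
        acc += g[i] * Fp(i + off, n);
        dFp(i + off, n) += w * g[i];
      }
      dK(m, n) = acc;
    }
  }
  return List::create(_["dFp"] = dFp, _["dK"] = dK);
}
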