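// Inner kernels of the network's training loop: same-padded temporal
// convolution (forward / backward, im2col + GEMM) and the pooling reductions
// of the attention blocks. Batches are carried as C x (T*B) matrices,
// column-major over (time, trial), matching the R side. The im2col matrix is
// built with raw-pointer copies and never crosses back into R: backward
// rebuilds it from the (much smaller) layer input.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// M (C*K x T*B): column (b*Tn + t) holds the K stacked C-blocks
// X[, b*Tn + t + k - P], k = 0..K-1, zero where t + k - P leaves the trial.
static void im2col_fill(const double* X, int C, int Tn, int B, int K,
                        arma::mat& M) {
  const int P = (K - 1) / 2;
  M.zeros();
  double* Mp = M.memptr();
  const arma::uword ldM = (arma::uword)C * K;
  for (int b = 0; b < B; ++b) {
    const double* Xb = X + (size_t)b * Tn * C;
    for (int t = 0; t < Tn; ++t) {
      double* col = Mp + (size_t)(b * Tn + t) * ldM;
      const int k0 = std::max(0, P - t);
      const int k1 = std::min(K - 1, Tn - 1 + P - t);
      if (k0 > k1) continue;
      // source columns t + k - P for k = k0..k1 are contiguous in Xb
      std::memcpy(col + (size_t)k0 * C, Xb + (size_t)(t + k0 - P) * C,
                  sizeof(double) * C * (k1 - k0 + 1));
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv1d_forward(const arma::mat& X, const arma::mat& W,
                             const arma::vec& bias, int Tn, int B, int K) {
  const int C = X.n_rows;
  arma::mat M((arma::uword)C * K, (arma::uword)Tn * B);
  im2col_fill(X.memptr(), C, Tn, B, K, M);
  arma::mat Y = W * M;
  Y.each_col() += bias;
  return Y;
}

// [[Rcpp::export]]
List cpp_conv1d_backward(const arma::mat& dY, const arma::mat& W,
                         const arma::mat& X, int Tn, int B, int K) {
  const int C = X.n_rows;
  const int P = (K - 1) / 2;
  arma::mat M((arma::uword)C * K, (arma::uword)Tn * B);
  im2col_fill(X.memptr(), C, Tn, B, K, M);
  arma::mat dW = dY * M.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dM = W.t() * dY;          // C*K x T*B
  arma::mat dX(C, (arma::uword)Tn * B, arma::fill::zeros);
  const double* dMp = dM.memptr();
  double* dXp = dX.memptr();
  const arma::uword ldM = (arma::uword)C * K;
  for (int b = 0; b < B; ++b) {
    double* dXb = dXp + (size_t)b * Tn * C;
    for (int t = 0; t < Tn; ++t) {
      const double* col = dMp + (size_t)(b * Tn + t) * ldM;
      const int k0 = std::max(0, P - t);
      const int k1 = std::min(K - 1, Tn - 1 + P - t);
      for (int k = k0; k <= k1; ++k) {
        double* dst = dXb + (size_t)(t + k - P) * C;
        const double* src = col + (size_t)k * C;
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
    }
  }
  return List::create(Named("dW") = dW, Named("db") = db, Named("dX") = dX);
}

// Per-trial pooling over the time axis: mean, max and argmax for each
// (channel, trial). A is C x (T*B).
// [[Rcpp::export]]
List cpp_pool_time(const arma::mat& A, int Tn, int B) {
  const int C = A.n_rows;
  arma::mat avg(C, B), mx(C, B);
  arma::imat arg(C, B);
  const double* Ap = A.memptr();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      double s = 0, m = Ap[(size_t)b * Tn * C + c];
      int am = 0;
      for (int t = 0; t < Tn; ++t) {
        double v = Ap[(size_t)(b * Tn + t) * C + c];
        s += v;
        if (v > m) { m = v; am = t; }
      }
      avg(c, b) = s / Tn;
      mx(c, b) = m;
      arg(c, b) = am + 1;  // 1-based for R
    }
  }
  return List::create(Named("avg") = avg, Named("max") = mx, Named("arg") = arg);
}

// Pooling over the channel axis: mean, max and argmax for each column (t, b).
// [[Rcpp::export]]
List cpp_pool_channel(const arma::mat& A) {
  const int C = A.n_rows;
  const arma::uword n = A.n_cols;
  arma::rowvec avg(n), mx(n);
  arma::irowvec arg(n);
  for (arma::uword j = 0; j < n; ++j) {
    double s = A(0, j), m = A(0, j);
    int am = 0;
    for (int c = 1; c < C; ++c) {
      double v = A(c, j);
      s += v;
      if (v > m) { m = v; am = c; }
    }
    avg(j) = s / C;
    mx(j) = m;
    arg(j) = am + 1;
  }
  return List::create(Named("avg") = avg, Named("max") = mx, Named("arg") = arg);
}

// ELU (alpha = 1) and its backward pass fused with the incoming gradient.
// [[Rcpp::export]]
arma::mat cpp_elu(const arma::mat& X) {
  arma::mat Y = X;
  double* p = Y.memptr();
  const size_t n = Y.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = std::expm1(p[i]);
  return Y;
}

// Returns dY * elu'(X) where Y = elu(X) (elu' = 1 for x > 0, else y + 1).
// [[Rcpp::export]]
arma::mat cpp_elu_backward(const arma::mat& dY, const arma::mat& X,
                           const arma::mat& Y) {
  arma::mat dX = dY;
  double* p = dX.memptr();
  const double* xp = X.memptr();
  const double* yp = Y.memptr();
  const size_t n = dX.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (xp[i] < 0) p[i] *= yp[i] + 1.0;
  return dX;
}

// Broadcast helpers for the attention gates. A is C x (T*B).

// Scale column j of A by s[j] (spatial gate over (t, b) locations).
// [[Rcpp::export]]
arma::mat cpp_scale_cols(const arma::mat& A, const arma::vec& s) {
  arma::mat Y = A;
  const int C = Y.n_rows;
  double* p = Y.memptr();
  for (arma::uword j = 0; j < Y.n_cols; ++j) {
    const double g = s(j);
    double* col = p + (size_t)j * C;
    for (int c = 0; c < C; ++c) col[c] *= g;
  }
  return Y;
}

// Multiply A[c, b*Tn + t] by G(c, b) (channel gate broadcast over time).
// [[Rcpp::export]]
arma::mat cpp_scale_bytrial(const arma::mat& A, const arma::mat& G, int Tn) {
  arma::mat Y = A;
  const int C = Y.n_rows;
  double* p = Y.memptr();
  for (arma::uword j = 0; j < Y.n_cols; ++j) {
    const double* g = G.colptr(j / Tn);
    double* col = p + (size_t)j * C;
    for (int c = 0; c < C; ++c) col[c] *= g[c];
  }
  return Y;
}

// A with v[j] added to every element of column j.
// [[Rcpp::export]]
arma::mat cpp_add_to_cols(const arma::mat& A, const arma::vec& v) {
  arma::mat Y = A;
  const int C = Y.n_rows;
  double* p = Y.memptr();
  for (arma::uword j = 0; j < Y.n_cols; ++j) {
    const double a = v(j);
    double* col = p + (size_t)j * C;
    for (int c = 0; c < C; ++c) col[c] += a;
  }
  return Y;
}

// A with G(c, b) added to A[c, b*Tn + t] for every t.
// [[Rcpp::export]]
arma::mat cpp_add_bytrial(const arma::mat& A, const arma::mat& G, int Tn) {
  arma::mat Y = A;
  const int C = Y.n_rows;
  double* p = Y.memptr();
  for (arma::uword j = 0; j < Y.n_cols; ++j) {
    const double* g = G.colptr(j / Tn);
    double* col = p + (size_t)j * C;
    for (int c = 0; c < C; ++c) col[c] += g[c];
  }
  return Y;
}

// Column sums of the element-wise product A .* B, without the temporary.
// [[Rcpp::export]]
arma::vec cpp_colsums_prod(const arma::mat& A, const arma::mat& B) {
  const int C = A.n_rows;
  arma::vec out(A.n_cols);
  const double* a = A.memptr();
  const double* b = B.memptr();
  for (arma::uword j = 0; j < A.n_cols; ++j) {
    double s = 0;
    const double* ca = a + (size_t)j * C;
    const double* cb = b + (size_t)j * C;
    for (int c = 0; c < C; ++c) s += ca[c] * cb[c];
    out(j) = s;
  }
  return out;
}
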