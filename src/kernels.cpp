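// Compute kernels for the sequence-model training engine.
//
// Feature maps are stored as R matrices of shape (C*L) x B, column-major,
// with the channel index varying fastest within a position:
//   x[(t-1)*C + c, b]  ==  channel c, position t, sample b.
// Convolutions use "same" padding (pad_l = floor((K-1)/2)) and are computed
// in single precision via im2col + GEMM; pooling truncates remainders.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::fmat as_fmat(const NumericMatrix& m) {
  arma::fmat out(m.nrow(), m.ncol());
  const double* src = m.begin();
  float* dst = out.memptr();
  const R_xlen_t n = (R_xlen_t)m.nrow() * m.ncol();
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return out;
}

static NumericMatrix as_rmat(const arma::fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  const float* src = m.memptr();
  double* dst = out.begin();
  const R_xlen_t n = (R_xlen_t)m.n_rows * m.n_cols;
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = (double)src[i];
  return out;
}

// im2col for the layout above: returns (C*K) x (L*B), column j = (b)*L + t.
static arma::fmat im2col(const arma::fmat& x, int C, int L, int K) {
  const int B = x.n_cols;
  const int pad_l = (K - 1) / 2;
  arma::fmat cols(C * K, (size_t)L * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const float* xb = x.colptr(b);
    for (int t = 0; t < L; ++t) {
      float* cj = cols.colptr((size_t)b * L + t);
      const int start = t - pad_l;
      for (int k = 0; k < K; ++k) {
        const int p = start + k;
        if (p >= 0 && p < L) {
          std::memcpy(cj + (size_t)k * C, xb + (size_t)p * C, C * sizeof(float));
        }
      }
    }
  }
  return cols;
}

static arma::fmat col2im(const arma::fmat& cols, int C, int L, int K, int B) {
  const int pad_l = (K - 1) / 2;
  arma::fmat x(C * L, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    float* xb = x.colptr(b);
    for (int t = 0; t < L; ++t) {
      const float* cj = cols.colptr((size_t)b * L + t);
      const int start = t - pad_l;
      for (int k = 0; k < K; ++k) {
        const int p = start + k;
        if (p >= 0 && p < L) {
          float* dst = xb + (size_t)p * C;
          const float* src = cj + (size_t)k * C;
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
  return x;
}

struct ConvCtx { arma::fmat cols; };

// [[Rcpp::export]]
List cpp_conv_forward(NumericMatrix x, NumericMatrix W,
                      NumericVector bias, int C, int L, int K,
                      bool want_ctx = false) {
  const int B = x.ncol();
  const int F = W.nrow();
  arma::fmat xf = as_fmat(x);
  arma::fmat Wf = as_fmat(W);
  arma::fmat cols = im2col(xf, C, L, K);
  arma::fmat Y = Wf * cols;                  // F x (L*B)
  arma::fvec bf(F);
  for (int f = 0; f < F; ++f) bf[f] = (float)bias[f];
  Y.each_col() += bf;
  Y.reshape((size_t)F * L, B);               // (F*L) x B, position-major blocks
  SEXP ctx = R_NilValue;
  if (want_ctx) {
    ConvCtx* c = new ConvCtx();
    c->cols = std::move(cols);
    ctx = Rcpp::XPtr<ConvCtx>(c, true);
  }
  return List::create(_["out"] = as_rmat(Y), _["ctx"] = ctx);
}

// [[Rcpp::export]]
List cpp_conv_backward(NumericMatrix x, NumericMatrix W, NumericMatrix dout,
                       int C, int L, int K, bool need_dx = true,
                       SEXP ctx = R_NilValue) {
  const int B = x.ncol();
  const int F = W.nrow();
  arma::fmat Wf = as_fmat(W);
  arma::fmat dY = as_fmat(dout);
  dY.reshape(F, (size_t)L * B);
  arma::fmat cols_local;
  const arma::fmat* colsp;
  if (ctx != R_NilValue) {
    Rcpp::XPtr<ConvCtx> cp(ctx);
    colsp = &cp->cols;
  } else {
    arma::fmat xf = as_fmat(x);
    cols_local = im2col(xf, C, L, K);
    colsp = &cols_local;
  }
  const arma::fmat& cols = *colsp;
  arma::fmat dW = dY * cols.t();             // F x (C*K)
  arma::fvec db = arma::sum(dY, 1);
  NumericVector dbv(F);
  for (int f = 0; f < F; ++f) dbv[f] = (double)db[f];
  if (!need_dx)
    return List::create(_["dx"] = R_NilValue, _["dW"] = as_rmat(dW),
                        _["db"] = dbv);
  arma::fmat dcols = Wf.t() * dY;            // (C*K) x (L*B)
  arma::fmat dx = col2im(dcols, C, L, K, B);
  return List::create(_["dx"] = as_rmat(dx), _["dW"] = as_rmat(dW),
                      _["db"] = dbv);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericMatrix x, int C, int L, int k) {
  const int B = x.ncol();
  const int Lout = L / k;                    // floor; remainder truncated
  NumericMatrix out(C * Lout, B);
  IntegerMatrix amax(C * Lout, B);
  for (int b = 0; b < B; ++b) {
    const double* xb = &x(0, b);
    double* ob = &out(0, b);
    int* ab = &amax(0, b);
    for (int t = 0; t < Lout; ++t) {
      for (int c = 0; c < C; ++c) {
        int best = (t * k) * C + c;
        double bv = xb[best];
        for (int j = 1; j < k; ++j) {
          const int idx = (t * k + j) * C + c;
          if (xb[idx] > bv) { bv = xb[idx]; best = idx; }
        }
        ob[t * C + c] = bv;
        ab[t * C + c] = best;                // 0-based row in the input map
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_backward(IntegerMatrix argmax, NumericMatrix dout,
                                   int C, int L) {
  const int B = dout.ncol();
  const int n = argmax.nrow();
  NumericMatrix dx(C * L, B);
  for (int b = 0; b < B; ++b) {
    const double* db = &dout(0, b);
    const int* ab = &argmax(0, b);
    double* xb = &dx(0, b);
    for (int i = 0; i < n; ++i) xb[ab[i]] += db[i];
  }
  return dx;
}

// Encode sequences (A,C,G,T only) as 0..3 integer codes, L x N.
// [[Rcpp::export]]
IntegerMatrix cpp_seq_to_codes(CharacterVector seqs) {
  const int N = seqs.size();
  if (N == 0) stop("no sequences");
  const int L = LENGTH(STRING_ELT(seqs, 0));
  IntegerMatrix codes(L, N);
  for (int i = 0; i < N; ++i) {
    SEXP s = STRING_ELT(seqs, i);
    if (LENGTH(s) != L) stop("sequences differ in length");
    const char* p = CHAR(s);
    for (int j = 0; j < L; ++j) {
      int v;
      switch (p[j]) {
        case 'A': case 'a': v = 0; break;
        case 'C': case 'c': v = 1; break;
        case 'G': case 'g': v = 2; break;
        case 'T': case 't': v = 3; break;
        default: stop("invalid character '%c' in sequence %d", p[j], i + 1);
      }
      codes(j, i) = v;
    }
  }
  return codes;
}

// One-hot encode a selection of sequences into the (4*L) x n engine layout.
// [[Rcpp::export]]
NumericMatrix cpp_codes_to_onehot(IntegerMatrix codes, IntegerVector sel) {
  const int L = codes.nrow();
  const int n = sel.size();
  NumericMatrix out(4 * L, n);
  for (int i = 0; i < n; ++i) {
    const int col = sel[i] - 1;
    if (col < 0 || col >= codes.ncol()) stop("selection out of range");
    double* ob = &out(0, i);
    for (int t = 0; t < L; ++t) ob[t * 4 + codes(t, col)] = 1.0;
  }
  return out;
}

// ---- batch normalization and ReLU (channel-fastest layout) ----

// [[Rcpp::export]]
List cpp_bn_forward_train(NumericMatrix x, int C, NumericVector gamma,
                          NumericVector beta, double eps) {
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  const R_xlen_t M = n / C;
  std::vector<double> mu(C, 0.0), m2(C, 0.0);
  const double* xp = x.begin();
  for (R_xlen_t i = 0; i < n; ) {
    for (int c = 0; c < C; ++c, ++i) {
      mu[c] += xp[i];
      m2[c] += xp[i] * xp[i];
    }
  }
  NumericVector mu_out(C), var_out(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    mu[c] /= M;
    double v = m2[c] / M - mu[c] * mu[c];
    if (v < 0) v = 0;
    mu_out[c] = mu[c];
    var_out[c] = v;
    invstd[c] = 1.0 / std::sqrt(v + eps);
  }
  NumericMatrix out(x.nrow(), x.ncol());
  double* op = out.begin();
  for (R_xlen_t i = 0; i < n; ) {
    for (int c = 0; c < C; ++c, ++i)
      op[i] = gamma[c] * (xp[i] - mu[c]) * invstd[c] + beta[c];
  }
  return List::create(_["out"] = out, _["mu"] = mu_out,
                      _["var"] = var_out, _["invstd"] = invstd);
}

// [[Rcpp::export]]
NumericMatrix cpp_bn_forward_eval(NumericMatrix x, int C,
                                  NumericVector gamma, NumericVector beta,
                                  NumericVector rm, NumericVector rv,
                                  double eps) {
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  NumericMatrix out(x.nrow(), x.ncol());
  std::vector<double> scale(C), shift(C);
  for (int c = 0; c < C; ++c) {
    scale[c] = gamma[c] / std::sqrt(rv[c] + eps);
    shift[c] = beta[c] - scale[c] * rm[c];
  }
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < n; ) {
    for (int c = 0; c < C; ++c, ++i) op[i] = scale[c] * xp[i] + shift[c];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bn_backward(NumericMatrix x, NumericMatrix dout, int C,
                     NumericVector gamma, NumericVector mu,
                     NumericVector invstd) {
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  const R_xlen_t M = n / C;
  std::vector<double> s1(C, 0.0), s2(C, 0.0);  // sum(dxhat), sum(dxhat*xhat)
  NumericVector dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* dp = dout.begin();
  for (R_xlen_t i = 0; i < n; ) {
    for (int c = 0; c < C; ++c, ++i) {
      const double xhat = (xp[i] - mu[c]) * invstd[c];
      const double dxhat = dp[i] * gamma[c];
      s1[c] += dxhat;
      s2[c] += dxhat * xhat;
      dgamma[c] += dp[i] * xhat;
      dbeta[c] += dp[i];
    }
  }
  NumericMatrix dx(x.nrow(), x.ncol());
  double* dxp = dx.begin();
  for (R_xlen_t i = 0; i < n; ) {
    for (int c = 0; c < C; ++c, ++i) {
      const double xhat = (xp[i] - mu[c]) * invstd[c];
      const double dxhat = dp[i] * gamma[c];
      dxp[i] = (invstd[c] / M) * (M * dxhat - s1[c] - xhat * s2[c]);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_forward(NumericMatrix x) {
  NumericMatrix out(x.nrow(), x.ncol());
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] > 0 ? xp[i] : 0.0;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_backward(NumericMatrix x, NumericMatrix dout) {
  NumericMatrix dx(x.nrow(), x.ncol());
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  const double* xp = x.begin();
  const double* dp = dout.begin();
  double* op = dx.begin();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] > 0 ? dp[i] : 0.0;
  return dx;
}


// Fused Adam update: returns new parameter, first and second moments.
// [[Rcpp::export]]
List cpp_adam_update(NumericVector p, NumericVector g, NumericVector m,
                     NumericVector v, double lr, double beta1, double beta2,
                     double bc1, double bc2, double eps) {
  const R_xlen_t n = p.size();
  NumericVector p2(n), m2(n), v2(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double mi = beta1 * m[i] + (1 - beta1) * g[i];
    const double vi = beta2 * v[i] + (1 - beta2) * g[i] * g[i];
    m2[i] = mi;
    v2[i] = vi;
    p2[i] = p[i] - lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
  p2.attr("dim") = p.attr("dim");
  return List::create(_["p"] = p2, _["m"] = m2, _["v"] = v2);
}

// Integer codes (1..4 = A,C,G,T), L x N -> character vector of sequences.
// [[Rcpp::export]]
CharacterVector cpp_codes_to_seq(IntegerMatrix codes) {
  static const char base[4] = {'A', 'C', 'G', 'T'};
  const int L = codes.nrow(), N = codes.ncol();
  CharacterVector out(N);
  std::string buf(L, 'A');
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < L; ++j) buf[j] = base[codes(j, i) - 1];
    out[i] = buf;
  }
  return out;
}
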