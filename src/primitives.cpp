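// Hot loops of the network: window gathering for convolution-as-GEMM,
// max pooling, and fused batch-norm + ReLU. Everything operates on
// flattened column-major arrays laid out as channels x positions x batch.
#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Gather every width-K window of a C x P x B array into a
// (C*K) x (P_out*B) column matrix, windows ordered position-major.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector X, int C, int P, int B, int K) {
  const int P_out = P - K + 1;
  NumericMatrix out(C * K, P_out * B);
  const double *x = X.begin();
  double *o = out.begin();
  const size_t win = (size_t)C * K;
  for (int b = 0; b < B; ++b) {
    const double *xb = x + (size_t)C * P * b;
    double *ob = o + win * P_out * b;
    for (int p = 0; p < P_out; ++p) {
      std::memcpy(ob + win * p, xb + (size_t)C * p, win * sizeof(double));
    }
  }
  return out;
}

// Transpose of cpp_im2col: scatter-add window gradients back onto the
// input layout.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dXcol, int C, int P, int B, int K) {
  const int P_out = P - K + 1;
  NumericVector dX((size_t)C * P * B);
  double *o = dX.begin();
  const double *d = dXcol.begin();
  const size_t win = (size_t)C * K;
  for (int b = 0; b < B; ++b) {
    double *ob = o + (size_t)C * P * b;
    const double *db = d + win * P_out * b;
    for (int p = 0; p < P_out; ++p) {
      const double *col = db + win * p;
      double *dst = ob + (size_t)C * p;
      for (size_t i = 0; i < win; ++i) dst[i] += col[i];
    }
  }
  return dX;
}

// Non-overlapping max pooling along positions of a C x P x B array;
// trailing partial windows are kept. Returns the pooled array and the
// within-window argmax (1-based) used by the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector A, int C, int P, int B, int pw) {
  const int n_win = (P + pw - 1) / pw;
  NumericVector out((size_t)C * n_win * B);
  IntegerVector arg((size_t)C * n_win * B);
  const double *a = A.begin();
  double *o = out.begin();
  int *g = arg.begin();
  for (int b = 0; b < B; ++b) {
    const double *ab = a + (size_t)C * P * b;
    double *ob = o + (size_t)C * n_win * b;
    int *gb = g + (size_t)C * n_win * b;
    for (int w = 0; w < n_win; ++w) {
      const int p0 = w * pw;
      const int jmax = std::min(pw, P - p0);
      double *ow = ob + (size_t)C * w;
      int *gw = gb + (size_t)C * w;
      std::memcpy(ow, ab + (size_t)C * p0, C * sizeof(double));
      for (int c = 0; c < C; ++c) gw[c] = 1;
      for (int j = 1; j < jmax; ++j) {
        const double *col = ab + (size_t)C * (p0 + j);
        for (int c = 0; c < C; ++c) {
          if (col[c] > ow[c]) { ow[c] = col[c]; gw[c] = j + 1; }
        }
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg, _["n_win"] = n_win);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dOut, IntegerVector arg,
                              int C, int P, int B, int pw) {
  const int n_win = (P + pw - 1) / pw;
  NumericVector dA((size_t)C * P * B);
  double *o = dA.begin();
  const double *d = dOut.begin();
  const int *g = arg.begin();
  for (int b = 0; b < B; ++b) {
    double *ob = o + (size_t)C * P * b;
    const double *db = d + (size_t)C * n_win * b;
    const int *gb = g + (size_t)C * n_win * b;
    for (int w = 0; w < n_win; ++w) {
      const int p0 = w * pw;
      for (int c = 0; c < C; ++c) {
        const int j = gb[(size_t)C * w + c];
        ob[(size_t)C * (p0 + j - 1) + c] += db[(size_t)C * w + c];
      }
    }
  }
  return dA;
}

// Fused train-mode batch normalization + ReLU over the rows (units) of
// an n x m matrix: per-row batch statistics, normalized activations,
// scale/shift, rectify. Returns the post-ReLU activations, the
// normalized values and statistics needed for the exact backward pass.
// [[Rcpp::export]]
List cpp_bn_relu_train(NumericMatrix Z, NumericVector gamma,
                       NumericVector beta, double eps) {
  const int n = Z.nrow(), m = Z.ncol();
  NumericVector mu(n), var(n), inv_sd(n);
  const double *z = Z.begin();
  for (int j = 0; j < m; ++j) {
    const double *col = z + (size_t)n * j;
    for (int i = 0; i < n; ++i) mu[i] += col[i];
  }
  for (int i = 0; i < n; ++i) mu[i] /= m;
  for (int j = 0; j < m; ++j) {
    const double *col = z + (size_t)n * j;
    for (int i = 0; i < n; ++i) {
      const double d = col[i] - mu[i];
      var[i] += d * d;
    }
  }
  for (int i = 0; i < n; ++i) {
    var[i] /= m;
    inv_sd[i] = 1.0 / std::sqrt(var[i] + eps);
  }
  NumericMatrix zhat(n, m), A(n, m);
  double *zh = zhat.begin(), *a = A.begin();
  for (int j = 0; j < m; ++j) {
    const double *col = z + (size_t)n * j;
    double *zcol = zh + (size_t)n * j;
    double *acol = a + (size_t)n * j;
    for (int i = 0; i < n; ++i) {
      const double v = (col[i] - mu[i]) * inv_sd[i];
      zcol[i] = v;
      const double y = gamma[i] * v + beta[i];
      acol[i] = y > 0 ? y : 0;
    }
  }
  return List::create(_["A"] = A, _["zhat"] = zhat, _["inv_sd"] = inv_sd,
                      _["mu"] = mu, _["var"] = var);
}

// Eval-mode batch normalization + ReLU using running moments.
// [[Rcpp::export]]
NumericMatrix cpp_bn_relu_eval(NumericMatrix Z, NumericVector gamma,
                               NumericVector beta, NumericVector run_mean,
                               NumericVector run_var, double eps) {
  const int n = Z.nrow(), m = Z.ncol();
  NumericVector scale(n), shift(n);
  for (int i = 0; i < n; ++i) {
    scale[i] = gamma[i] / std::sqrt(run_var[i] + eps);
    shift[i] = beta[i] - run_mean[i] * scale[i];
  }
  NumericMatrix A(n, m);
  const double *z = Z.begin();
  double *a = A.begin();
  for (int j = 0; j < m; ++j) {
    const double *col = z + (size_t)n * j;
    double *acol = a + (size_t)n * j;
    for (int i = 0; i < n; ++i) {
      const double y = scale[i] * col[i] + shift[i];
      acol[i] = y > 0 ? y : 0;
    }
  }
  return A;
}

// Backward through ReLU (mask from the post-ReLU activations) and
// train-mode batch normalization, whose batch statistics are part of
// the computation graph.
// [[Rcpp::export]]
List cpp_bn_relu_bwd(NumericMatrix dA, NumericMatrix A, NumericMatrix zhat,
                     NumericVector inv_sd, NumericVector gamma) {
  const int n = dA.nrow(), m = dA.ncol();
  NumericVector s1(n), s2(n);
  const double *da = dA.begin(), *a = A.begin(), *zh = zhat.begin();
  for (int j = 0; j < m; ++j) {
    const size_t off = (size_t)n * j;
    for (int i = 0; i < n; ++i) {
      if (a[off + i] > 0) {
        const double d = da[off + i];
        s1[i] += d;
        s2[i] += d * zh[off + i];
      }
    }
  }
  NumericMatrix dZ(n, m);
  double *dz = dZ.begin();
  for (int j = 0; j < m; ++j) {
    const size_t off = (size_t)n * j;
    for (int i = 0; i < n; ++i) {
      const double d = a[off + i] > 0 ? da[off + i] : 0.0;
      dz[off + i] = inv_sd[i] * gamma[i] / m *
        (m * d - s1[i] - zh[off + i] * s2[i]);
    }
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = s2, _["dbeta"] = s1);
}
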