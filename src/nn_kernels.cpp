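// Low-level numerical kernels: dilated 1-D convolution (same padding),
// factor-2 max pooling, stride-2 transposed convolution, and a direct-form
// II transposed IIR filter with initial conditions.  Tensors are cubes with
// dims (channels, length, batch).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// W has dims (C_out, C_in * k); tap t occupies columns [t*C_in, (t+1)*C_in).
// [[Rcpp::export]]
arma::cube cpp_conv1d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int k, int dilation) {
  const int Cin = x.n_rows, L = x.n_cols, N = x.n_slices;
  const int Cout = W.n_rows, c = (k - 1) / 2;
  cube y(Cout, L, N, fill::zeros);
  for (int n = 0; n < N; ++n) {
    mat& xs = const_cast<cube&>(x).slice(n);
    mat& ys = y.slice(n);
    for (int t = 0; t < k; ++t) {
      const int off = (t - c) * dilation;
      const mat Wt = W.cols(t * Cin, (t + 1) * Cin - 1);
      if (off >= 0) {
        if (off < L) ys.cols(0, L - 1 - off) += Wt * xs.cols(off, L - 1);
      } else {
        if (-off < L) ys.cols(-off, L - 1) += Wt * xs.cols(0, L - 1 + off);
      }
    }
    ys.each_col() += b;
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bwd(const arma::cube& x, const arma::mat& W,
                          const arma::cube& gy, int k, int dilation) {
  const int Cin = x.n_rows, L = x.n_cols, N = x.n_slices;
  const int c = (k - 1) / 2;
  cube gx(Cin, L, N, fill::zeros);
  mat gW(W.n_rows, W.n_cols, fill::zeros);
  vec gb(W.n_rows, fill::zeros);
  for (int n = 0; n < N; ++n) {
    mat& xs = const_cast<cube&>(x).slice(n);
    mat& gs = const_cast<cube&>(gy).slice(n);
    gb += sum(gs, 1);
    for (int t = 0; t < k; ++t) {
      const int off = (t - c) * dilation;
      const mat Wt = W.cols(t * Cin, (t + 1) * Cin - 1);
      if (off >= 0) {
        if (off < L) {
          gx.slice(n).cols(off, L - 1) += Wt.t() * gs.cols(0, L - 1 - off);
          gW.cols(t * Cin, (t + 1) * Cin - 1) +=
            gs.cols(0, L - 1 - off) * xs.cols(off, L - 1).t();
        }
      } else {
        if (-off < L) {
          gx.slice(n).cols(0, L - 1 + off) += Wt.t() * gs.cols(-off, L - 1);
          gW.cols(t * Cin, (t + 1) * Cin - 1) +=
            gs.cols(-off, L - 1) * xs.cols(0, L - 1 + off).t();
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
Rcpp::List cpp_pool2_fwd(const arma::cube& x) {
  const int C = x.n_rows, L = x.n_cols, N = x.n_slices, Lo = L / 2;
  cube y(C, Lo, N);
  ucube idx(C, Lo, N);  // 0 if first sample of the pair won, 1 otherwise
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < Lo; ++j)
      for (int cch = 0; cch < C; ++cch) {
        const double a = x(cch, 2 * j, n), bb = x(cch, 2 * j + 1, n);
        // ties take the earlier sample for determinism
        if (a >= bb) { y(cch, j, n) = a;  idx(cch, j, n) = 0; }
        else         { y(cch, j, n) = bb; idx(cch, j, n) = 1; }
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_pool2_bwd(const arma::cube& g, const arma::ucube& idx) {
  const int C = g.n_rows, Lo = g.n_cols, N = g.n_slices;
  cube gx(C, 2 * Lo, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < Lo; ++j)
      for (int cch = 0; cch < C; ++cch)
        gx(cch, 2 * j + idx(cch, j, n), n) = g(cch, j, n);
  return gx;
}

// Transposed convolution, kernel 2 stride 2: output sample 2j comes from
// W0 * x_j, sample 2j+1 from W1 * x_j.
// [[Rcpp::export]]
arma::cube cpp_upconv2_fwd(const arma::cube& x, const arma::mat& W0,
                           const arma::mat& W1, const arma::vec& b) {
  const int L = x.n_cols, N = x.n_slices, Cout = W0.n_rows;
  cube y(Cout, 2 * L, N);
  for (int n = 0; n < N; ++n) {
    mat& xs = const_cast<cube&>(x).slice(n);
    mat e = W0 * xs, o = W1 * xs;
    e.each_col() += b; o.each_col() += b;
    for (int j = 0; j < L; ++j) {
      y.slice(n).col(2 * j) = e.col(j);
      y.slice(n).col(2 * j + 1) = o.col(j);
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_upconv2_bwd(const arma::cube& x, const arma::mat& W0,
                           const arma::mat& W1, const arma::cube& gy) {
  const int Cin = x.n_rows, L = x.n_cols, N = x.n_slices;
  cube gx(Cin, L, N);
  mat gW0(W0.n_rows, W0.n_cols, fill::zeros);
  mat gW1(W1.n_rows, W1.n_cols, fill::zeros);
  vec gb(W0.n_rows, fill::zeros);
  for (int n = 0; n < N; ++n) {
    mat ge(W0.n_rows, L), go(W0.n_rows, L);
    for (int j = 0; j < L; ++j) {
      ge.col(j) = gy.slice(n).col(2 * j);
      go.col(j) = gy.slice(n).col(2 * j + 1);
    }
    mat& xs = const_cast<cube&>(x).slice(n);
    gW0 += ge * xs.t();
    gW1 += go * xs.t();
    gb += sum(ge, 1) + sum(go, 1);
    gx.slice(n) = W0.t() * ge + W1.t() * go;
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW0") = gW0,
                            Rcpp::Named("gW1") = gW1,
                            Rcpp::Named("gb") = gb);
}

// Direct-form II transposed linear filter with initial state zi
// (length max(len(a), len(b)) - 1); a[0] must be 1.
// [[Rcpp::export]]
arma::vec cpp_lfilter(const arma::vec& b, const arma::vec& a,
                      const arma::vec& x, const arma::vec& zi) {
  const int n = x.n_elem, m = std::max(a.n_elem, b.n_elem);
  vec bb(m, fill::zeros), aa(m, fill::zeros);
  bb.head(b.n_elem) = b; aa.head(a.n_elem) = a;
  vec z(m, fill::zeros);  // one guard slot at the end
  if (zi.n_elem) z.head(zi.n_elem) = zi;
  vec y(n);
  for (int i = 0; i < n; ++i) {
    const double yi = bb[0] * x[i] + z[0];
    for (int j = 0; j < m - 1; ++j)
      z[j] = bb[j + 1] * x[i] + z[j + 1] - aa[j + 1] * yi;
    y[i] = yi;
  }
  return y;
}
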