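// Dense numerical kernels for the in-package neural networks:
// 1-D convolution (forward, input-gradient, weight-gradient) and a
// single-layer LSTM (forward with cached gates, backward through time).
//
// Layout conventions, shared with the R orchestration code:
//  - batched sequences are cubes (batch B, time L, channels C);
//  - conv weights are (k*Cin x Cout), row index tau*Cin + cin;
//  - LSTM gate order within the 4H axis is i, f, g, o;
//  - LSTM per-step matrices are returned stacked as (B*T x H), rows
//    ordered batch-fastest, which matches R's array(x, c(B, T, H)).
// Transposed convolutions are expressed by the R callers as the adjoint of
// these kernels (conv_bw_input as forward, conv_fw as input-gradient).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat gather_time(const cube& x, uword t) {
  // (B x C) slab of a (B,L,C) cube at time t
  mat m(x.n_rows, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c) m.col(c) = x.slice(c).col(t);
  return m;
}

static inline mat im2col_t(const cube& x, uword t, uword k, uword stride,
                           int padl) {
  const uword B = x.n_rows, L = x.n_cols, Cin = x.n_slices;
  mat M(B, k * Cin, fill::zeros);
  for (uword tau = 0; tau < k; ++tau) {
    const int p = static_cast<int>(t * stride) - padl + static_cast<int>(tau);
    if (p < 0 || p >= static_cast<int>(L)) continue;
    for (uword c = 0; c < Cin; ++c)
      M.col(tau * Cin + c) = x.slice(c).col(static_cast<uword>(p));
  }
  return M;
}

// Forward convolution; `bias` (length Cout, possibly all zero) is added
// per output channel here to avoid a broadcast allocation in R.
// [[Rcpp::export]]
arma::cube cpp_conv1d_fw(const arma::cube& x, const arma::mat& W,
                         const arma::vec& bias, int stride, int padl,
                         int Lout) {
  const uword B = x.n_rows, Cin = x.n_slices, Cout = W.n_cols;
  const uword k = W.n_rows / Cin;
  cube y(B, static_cast<uword>(Lout), Cout, fill::zeros);
  for (uword t = 0; t < static_cast<uword>(Lout); ++t) {
    mat Y = im2col_t(x, t, k, stride, padl) * W;
    for (uword c = 0; c < Cout; ++c) y.slice(c).col(t) = Y.col(c) + bias(c);
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_bw_input(const arma::cube& dy, const arma::mat& W,
                               const arma::vec& bias, int stride, int padl,
                               int L, int Cin) {
  const uword B = dy.n_rows, Lout = dy.n_cols;
  const uword k = W.n_rows / static_cast<uword>(Cin);
  cube dx(B, static_cast<uword>(L), static_cast<uword>(Cin), fill::zeros);
  for (uword t = 0; t < Lout; ++t) {
    mat M = gather_time(dy, t) * W.t();   // (B x k*Cin)
    for (uword tau = 0; tau < k; ++tau) {
      const int p = static_cast<int>(t) * stride - padl + static_cast<int>(tau);
      if (p < 0 || p >= L) continue;
      for (uword c = 0; c < static_cast<uword>(Cin); ++c)
        dx.slice(c).col(static_cast<uword>(p)) += M.col(tau * static_cast<uword>(Cin) + c);
    }
  }
  for (uword c = 0; c < static_cast<uword>(Cin); ++c) dx.slice(c) += bias(c);
  return dx;
}

// [[Rcpp::export]]
arma::mat cpp_conv1d_bw_weight(const arma::cube& x, const arma::cube& dy,
                               int k, int stride, int padl) {
  const uword Cin = x.n_slices, Cout = dy.n_slices, Lout = dy.n_cols;
  mat dW(static_cast<uword>(k) * Cin, Cout, fill::zeros);
  for (uword t = 0; t < Lout; ++t)
    dW += im2col_t(x, t, static_cast<uword>(k), stride, padl).t() * gather_time(dy, t);
  return dW;
}

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// [[Rcpp::export]]
Rcpp::List cpp_lstm_fw(const arma::cube& x, const arma::mat& W,
                       const arma::mat& U, const arma::vec& b) {
  const uword B = x.n_rows, T = x.n_cols, Din = x.n_slices, H = U.n_rows;
  mat Xm(B * T, Din);
  for (uword d = 0; d < Din; ++d) Xm.col(d) = vectorise(x.slice(d));
  const mat XW = Xm * W;                   // (B*T x 4H)
  mat h(B * T, H), c(B * T, H), gi(B * T, H), gf(B * T, H),
      gg(B * T, H), go(B * T, H);
  mat h_prev(B, H, fill::zeros), c_prev(B, H, fill::zeros);
  const rowvec br = b.t();
  for (uword t = 0; t < T; ++t) {
    mat A = XW.rows(t * B, (t + 1) * B - 1) + h_prev * U;
    A.each_row() += br;
    const mat i = sigm(A.cols(0, H - 1));
    const mat f = sigm(A.cols(H, 2 * H - 1));
    const mat g = tanh(A.cols(2 * H, 3 * H - 1));
    const mat o = sigm(A.cols(3 * H, 4 * H - 1));
    const mat ct = f % c_prev + i % g;
    const mat ht = o % tanh(ct);
    gi.rows(t * B, (t + 1) * B - 1) = i;
    gf.rows(t * B, (t + 1) * B - 1) = f;
    gg.rows(t * B, (t + 1) * B - 1) = g;
    go.rows(t * B, (t + 1) * B - 1) = o;
    c.rows(t * B, (t + 1) * B - 1) = ct;
    h.rows(t * B, (t + 1) * B - 1) = ht;
    h_prev = ht; c_prev = ct;
  }
  return Rcpp::List::create(Rcpp::Named("h") = h, Rcpp::Named("c") = c,
                            Rcpp::Named("i") = gi, Rcpp::Named("f") = gf,
                            Rcpp::Named("g") = gg, Rcpp::Named("o") = go);
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_bw(const arma::cube& x, const arma::mat& W,
                       const arma::mat& U, const arma::mat& h,
                       const arma::mat& c, const arma::mat& gi,
                       const arma::mat& gf, const arma::mat& gg,
                       const arma::mat& go, const arma::mat& dh_out) {
  const uword B = x.n_rows, T = x.n_cols, Din = x.n_slices, H = U.n_rows;
  mat Xm(B * T, Din);
  for (uword d = 0; d < Din; ++d) Xm.col(d) = vectorise(x.slice(d));
  mat dW(Din, 4 * H, fill::zeros), dU(H, 4 * H, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  mat dXm(B * T, Din);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const uword r0 = tt * B, r1 = (tt + 1) * B - 1;
    const mat i = gi.rows(r0, r1), f = gf.rows(r0, r1),
              g = gg.rows(r0, r1), o = go.rows(r0, r1),
              ct = c.rows(r0, r1);
    const mat tc = tanh(ct);
    const mat c_prev = (tt == 0) ? mat(B, H, fill::zeros)
                                 : mat(c.rows(r0 - B, r0 - 1));
    const mat h_prev = (tt == 0) ? mat(B, H, fill::zeros)
                                 : mat(h.rows(r0 - B, r0 - 1));
    const mat dh = dh_out.rows(r0, r1) + dh_next;
    const mat dc = dh % o % (1.0 - tc % tc) + dc_next;
    mat dA(B, 4 * H);
    dA.cols(0, H - 1)         = dc % g % i % (1.0 - i);
    dA.cols(H, 2 * H - 1)     = dc % c_prev % f % (1.0 - f);
    dA.cols(2 * H, 3 * H - 1) = dc % i % (1.0 - g % g);
    dA.cols(3 * H, 4 * H - 1) = dh % tc % o % (1.0 - o);
    dW += Xm.rows(r0, r1).t() * dA;
    dU += h_prev.t() * dA;
    db += sum(dA, 0);
    dXm.rows(r0, r1) = dA * W.t();
    dh_next = dA * U.t();
    dc_next = dc % f;
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dXm, Rcpp::Named("dW") = dW,
                            Rcpp::Named("dU") = dU,
                            Rcpp::Named("db") = vec(db.t()));
}
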