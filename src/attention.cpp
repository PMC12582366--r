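// Batched multi-head attention kernels.
//
// The encoder processes a batch of B sequences padded to T tokens as a
// (B*T) x d matrix in sequence-major order.  Scaled-dot-product attention is
// the only part of the network that cannot be expressed as one large BLAS
// call per layer (it is block-diagonal over sequences), so the per-sequence,
// per-head loops live here.  Probabilities for pad columns are exactly zero.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Qr, Kr, V: (B*T) x d row-major-by-sequence stacks (RoPE already applied to
// Qr/Kr).  valid: B x T 0/1 matrix marking real (non-pad) tokens.
// Returns ctx (B*T) x d and the attention probabilities as a (T*T) x (B*nh)
// matrix (column = one flattened T x T matrix, sequence-major then head).
// [[Rcpp::export]]
Rcpp::List attn_forward_cpp(const arma::mat& Qr, const arma::mat& Kr,
                            const arma::mat& V, const arma::imat& valid,
                            int B, int T, int nh) {
  const int d = Qr.n_cols;
  const int dh = d / nh;
  const double scale = 1.0 / std::sqrt((double) dh);
  mat ctx(B * T, d, fill::zeros);
  mat Astore(T * T, (size_t) B * nh);

  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword) b * T, r1 = r0 + T - 1;
    bool all_valid = true;
    for (int t = 0; t < T; ++t) if (valid(b, t) == 0) { all_valid = false; break; }
    for (int h = 0; h < nh; ++h) {
      const uword c0 = (uword) h * dh, c1 = c0 + dh - 1;
      mat S = Qr.submat(r0, c0, r1, c1) * Kr.submat(r0, c0, r1, c1).t() * scale;
      if (!all_valid) {
        for (int t = 0; t < T; ++t) {
          if (valid(b, t) == 0) S.col(t).fill(-datum::inf);
        }
      }
      vec m = max(S, 1);
      S.each_col() -= m;
      mat A = exp(S);
      vec rs = sum(A, 1);
      A.each_col() /= rs;
      ctx.submat(r0, c0, r1, c1) = A * V.submat(r0, c0, r1, c1);
      Astore.col((size_t) b * nh + h) = vectorise(A);
    }
  }
  return Rcpp::List::create(Rcpp::Named("ctx") = ctx,
                            Rcpp::Named("A") = Astore);
}

// Backward pass of the same attention.  dctx: (B*T) x d upstream gradient;
// A: probabilities as returned by attn_forward_cpp.
// [[Rcpp::export]]
Rcpp::List attn_backward_cpp(const arma::mat& dctx, const arma::mat& Astore,
                             const arma::mat& Qr, const arma::mat& Kr,
                             const arma::mat& V, int B, int T, int nh) {
  const int d = Qr.n_cols;
  const int dh = d / nh;
  const double scale = 1.0 / std::sqrt((double) dh);
  mat dQr(B * T, d, fill::zeros), dKr(B * T, d, fill::zeros),
      dV(B * T, d, fill::zeros);

  for (int b = 0; b < B; ++b) {
    const uword r0 = (uword) b * T, r1 = r0 + T - 1;
    for (int h = 0; h < nh; ++h) {
      const uword c0 = (uword) h * dh, c1 = c0 + dh - 1;
      const mat A(const_cast<double*>(Astore.colptr((size_t) b * nh + h)),
                  T, T, false, true);
      mat dctx_bh = dctx.submat(r0, c0, r1, c1);
      mat Vb = V.submat(r0, c0, r1, c1);
      mat dA = dctx_bh * Vb.t();
      dV.submat(r0, c0, r1, c1) = A.t() * dctx_bh;
      vec rowdot = sum(dA % A, 1);
      mat dS = A % (dA.each_col() - rowdot);
      dQr.submat(r0, c0, r1, c1) = dS * Kr.submat(r0, c0, r1, c1) * scale;
      dKr.submat(r0, c0, r1, c1) = dS.t() * Qr.submat(r0, c0, r1, c1) * scale;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQr") = dQr,
                            Rcpp::Named("dKr") = dKr,
                            Rcpp::Named("dV") = dV);
}

// ---- elementwise / rowwise primitives used by every layer ----

// tanh-approximation GELU; returns the activation and its derivative in one
// pass so the backward step never recomputes tanh.
// [[Rcpp::export]]
Rcpp::List gelu_fwd_cpp(const arma::mat& x) {
  const double c1 = 0.7978845608028654, c2 = 0.044715;
  mat u = c1 * (x + c2 * (x % x % x));
  mat t = tanh(u);
  mat y = 0.5 * x % (1 + t);
  mat g = 0.5 * (1 + t) + (0.5 * c1) * x % (1 - t % t) % (1 + 3 * c2 * square(x));
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("g") = g);
}

// [[Rcpp::export]]
Rcpp::List ln_fwd_cpp(const arma::mat& X, const arma::vec& g,
                      const arma::vec& b, double eps) {
  vec mu = mean(X, 1);
  mat Xc = X.each_col() - mu;
  vec inv_sd = 1.0 / sqrt(mean(Xc % Xc, 1) + eps);
  mat xhat = Xc.each_col() % inv_sd;
  mat y = xhat.each_row() % g.t();
  y.each_row() += b.t();
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv_sd") = inv_sd);
}

// [[Rcpp::export]]
Rcpp::List ln_bwd_cpp(const arma::mat& dy, const arma::mat& xhat,
                      const arma::vec& inv_sd, const arma::vec& g) {
  mat dxhat = dy.each_row() % g.t();
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  mat dx = dxhat.each_col() - m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= inv_sd;
  rowvec dg = sum(dy % xhat, 0);
  rowvec db = sum(dy, 0);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dg") = dg.t(),
                            Rcpp::Named("db") = db.t());
}

// Rotary embedding over all heads at once.  X is (B*T) x d sequence-major;
// cosTab/sinTab are T x dh with each angle duplicated across the dimension
// pair.  inverse = true applies the transpose rotation (backward pass).
// [[Rcpp::export]]
arma::mat rope_all_cpp(const arma::mat& X, const arma::mat& cosTab,
                       const arma::mat& sinTab, int nh, int T, bool inverse) {
  const int n = X.n_rows, d = X.n_cols, dh = d / nh;
  const double sgn = inverse ? -1.0 : 1.0;
  mat out(n, d);
  for (int i = 0; i < n; ++i) {
    const int p = i % T;
    for (int h = 0; h < nh; ++h) {
      const int off = h * dh;
      for (int j = 0; j < dh; j += 2) {
        const double c = cosTab(p, j), s = sgn * sinTab(p, j);
        const double x1 = X(i, off + j), x2 = X(i, off + j + 1);
        out(i, off + j) = x1 * c - x2 * s;
        out(i, off + j + 1) = x2 * c + x1 * s;
      }
    }
  }
  return out;
}
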