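// Hot paths of the state-space machinery: exact fixed-interval Kalman
// smoothing with per-day missing-data patterns, the expected complete-data
// Gaussian criterion of the EM covariance step, the GLS accumulation for the
// regression coefficients, and per-day conditional-normal (kriging)
// prediction. Missing entries are encoded as NaN.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// Kalman filter + Rauch-Tung-Striebel smoother for
//   z_t = G z_{t-1} + eta_t,  y_t = mu_t + H_t z_t + e_t,
// with e_t ~ N(0, Sigma[obs_t, obs_t]) and z_0 ~ N(a0, P0).
// Y, mu: N x T (NaN = missing). Returns smoothed states for t = 0..T,
// smoothed covariances, lag-one covariances Cov(z_t, z_{t-1} | Y) for
// t = 1..T, and the marginal log-likelihood.
// [[Rcpp::export]]
Rcpp::List cpp_kalman_smoother(const arma::mat& Y, const arma::mat& mu,
                               const arma::mat& H, const arma::mat& Sigma,
                               const arma::mat& G, const arma::mat& Q,
                               const arma::vec& a0, const arma::mat& P0) {
  const uword T = Y.n_cols, p = G.n_rows;
  mat af(p, T + 1), ap(p, T);
  cube Pf(p, p, T + 1), Pp(p, p, T);
  af.col(0) = a0; Pf.slice(0) = P0;
  double ll = 0.0;

  vec a = a0; mat P = P0;
  for (uword t = 0; t < T; ++t) {
    vec apred = G * a;
    mat Ppred = symmatu(G * P * G.t() + Q);
    ap.col(t) = apred; Pp.slice(t) = Ppred;

    uvec idx = find_finite(Y.col(t));
    if (idx.n_elem > 0) {
      mat Ht = H.rows(idx);
      vec v = Y.col(t); v = v(idx);
      vec m = mu.col(t); m = m(idx);
      v -= m + Ht * apred;
      mat F = symmatu(Ht * Ppred * Ht.t() + Sigma.submat(idx, idx));
      mat L;
      if (!chol(L, F, "lower")) {
        F.diag() += 1e-8;
        L = chol(F, "lower");
      }
      vec w1 = solve(trimatl(L), v);
      mat PHt = Ppred * Ht.t();                 // p x n
      mat M = solve(trimatl(L), PHt.t());       // n x p
      ll += -0.5 * (idx.n_elem * LOG2PI) - accu(log(L.diag())) - 0.5 * dot(w1, w1);
      a = apred + M.t() * w1;
      P = symmatu(Ppred - M.t() * M);
    } else {
      a = apred; P = Ppred;
    }
    af.col(t + 1) = a; Pf.slice(t + 1) = P;
  }

  // RTS smoother
  mat zs(p, T + 1); cube Ps(p, p, T + 1), Plag(p, p, T);
  zs.col(T) = af.col(T); Ps.slice(T) = Pf.slice(T);
  for (uword t = T; t-- > 0;) {
    mat Ppred = Pp.slice(t);
    mat J;
    mat Pinv;
    if (!inv_sympd(Pinv, symmatu(Ppred + 1e-12 * eye(p, p))))
      Pinv = pinv(symmatu(Ppred));
    J = Pf.slice(t) * G.t() * Pinv;
    zs.col(t) = af.col(t) + J * (zs.col(t + 1) - ap.col(t));
    Ps.slice(t) = symmatu(Pf.slice(t) + J * (Ps.slice(t + 1) - Ppred) * J.t());
    Plag.slice(t) = Ps.slice(t + 1) * J.t();   // Cov(z_{t+1}, z_t | Y)
  }

  return Rcpp::List::create(
    Rcpp::Named("z") = zs, Rcpp::Named("P") = Ps,
    Rcpp::Named("Plag") = Plag, Rcpp::Named("loglik") = ll);
}

// Expected complete-data Gaussian criterion for the covariance step:
//   sum_t [ log|Sigma_t| + tr(Sigma_t^{-1} (r_t r_t' + H_t P_t H_t')) ]
// where r_t = E.col(t) over observed entries (NaN = missing) and P_t is the
// smoothed state covariance of day t (slice t of PT, slices 1..T used).
// [[Rcpp::export]]
double cpp_gauss_Q(const arma::mat& E, const arma::mat& H,
                   const arma::cube& PT, const arma::mat& Sigma) {
  const uword T = E.n_cols;
  double q = 0.0;
  for (uword t = 0; t < T; ++t) {
    uvec idx = find_finite(E.col(t));
    if (idx.n_elem == 0) continue;
    vec r = E.col(t); r = r(idx);
    mat S = Sigma.submat(idx, idx);
    mat L;
    if (!chol(L, S, "lower")) {
      S.diag() += 1e-8;
      if (!chol(L, S, "lower")) return datum::inf;
    }
    vec w = solve(trimatl(L), r);
    mat M = solve(trimatl(L), H.rows(idx));     // n x p
    q += 2.0 * accu(log(L.diag())) + dot(w, w) +
      accu((M * PT.slice(t + 1)) % M);
  }
  return q;
}

// As cpp_gauss_Q, but also accumulates the weight matrix
//   W = sum_t scatter( S_t^{-1} - S_t^{-1} A_t S_t^{-1} )
// with A_t = r_t r_t' + H_t P_t H_t', so that the gradient of Q with
// respect to any covariance parameter is accu(W % dSigma/dtheta).
// [[Rcpp::export]]
Rcpp::List cpp_gauss_Q_grad(const arma::mat& E, const arma::mat& H,
                            const arma::cube& PT, const arma::mat& Sigma) {
  const uword N = E.n_rows, T = E.n_cols;
  double q = 0.0;
  mat W(N, N, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    uvec idx = find_finite(E.col(t));
    if (idx.n_elem == 0) continue;
    vec r = E.col(t); r = r(idx);
    mat S = Sigma.submat(idx, idx);
    mat L;
    if (!chol(L, S, "lower")) {
      S.diag() += 1e-8;
      if (!chol(L, S, "lower"))
        return Rcpp::List::create(Rcpp::Named("Q") = datum::inf,
                                  Rcpp::Named("W") = W);
    }
    vec w = solve(trimatl(L), r);
    mat M = solve(trimatl(L), H.rows(idx));
    const mat& Pt = PT.slice(t + 1);
    q += 2.0 * accu(log(L.diag())) + dot(w, w) + accu((M * Pt) % M);
    mat Li = inv(trimatl(L));
    mat Sinv = Li.t() * Li;
    vec sr = Sinv * r;                       // S^-1 r
    mat SH = Sinv * H.rows(idx);             // S^-1 H_t
    mat Wt = Sinv - sr * sr.t() - SH * Pt * SH.t();
    W.submat(idx, idx) += Wt;
  }
  return Rcpp::List::create(Rcpp::Named("Q") = q, Rcpp::Named("W") = W);
}

// GLS accumulation for the regression coefficients given smoothed states:
// returns A = sum_t X_t' S_t^{-1} X_t and b = sum_t X_t' S_t^{-1} r_t,
// with r_t the (y - H z) residual (NaN = missing) and X the design cube.
// [[Rcpp::export]]
Rcpp::List cpp_beta_gls(const arma::mat& R, const arma::cube& X,
                        const arma::mat& Sigma) {
  const uword T = R.n_cols, b = X.n_cols;
  mat A(b, b, fill::zeros);
  vec rhs(b, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    uvec idx = find_finite(R.col(t));
    if (idx.n_elem == 0) continue;
    vec r = R.col(t); r = r(idx);
    mat Xt = X.slice(t); Xt = Xt.rows(idx);
    mat S = Sigma.submat(idx, idx);
    mat L;
    if (!chol(L, S, "lower")) { S.diag() += 1e-8; L = chol(S, "lower"); }
    mat M = solve(trimatl(L), Xt);
    vec w = solve(trimatl(L), r);
    A += M.t() * M;
    rhs += M.t() * w;
  }
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("b") = rhs);
}

// Per-day conditional-normal prediction at n0 target entries.
// E: N x T kriging residual (y - X beta - H zT, NaN = missing);
// C0: n0 x N cross-covariance (no nugget); c0: n0 prior spatial variances;
// H0: n0 x p target loadings; PT: smoothed state covariances (slices 1..T).
// Returns the conditional-mean adjustment (to be added to mu0 + H0 zT) and
// the prediction variance (spatial conditional + state-uncertainty term).
// [[Rcpp::export]]
Rcpp::List cpp_krige(const arma::mat& E, const arma::mat& H,
                     const arma::mat& Sigma, const arma::mat& C0,
                     const arma::vec& c0, const arma::mat& H0,
                     const arma::cube& PT) {
  const uword T = E.n_cols, n0 = C0.n_rows;
  mat adj(n0, T, fill::zeros), vr(n0, T);
  for (uword t = 0; t < T; ++t) {
    uvec idx = find_finite(E.col(t));
    const mat& Pt = PT.slice(t + 1);
    if (idx.n_elem == 0) {
      adj.col(t).zeros();
      vr.col(t) = c0 + sum((H0 * Pt) % H0, 1);
      continue;
    }
    vec r = E.col(t); r = r(idx);
    mat S = Sigma.submat(idx, idx);
    mat L;
    if (!chol(L, S, "lower")) { S.diag() += 1e-8; L = chol(S, "lower"); }
    mat Ct = C0.cols(idx);                       // n0 x n
    mat M = solve(trimatl(L), Ct.t());           // n x n0
    vec w = solve(trimatl(L), r);                // n
    adj.col(t) = M.t() * w;
    mat Ht = H.rows(idx);
    mat MH = solve(trimatl(L), Ht);              // n x p
    mat B = H0 - M.t() * MH;                     // n0 x p
    vec vsp = c0 - sum(M % M, 0).t();
    vr.col(t) = clamp(vsp, 0.0, datum::inf) + sum((B * Pt) % B, 1);
  }
  vr = clamp(vr, 0.0, datum::inf);
  return Rcpp::List::create(Rcpp::Named("adj") = adj, Rcpp::Named("var") = vr);
}
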