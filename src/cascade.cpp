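// Numerical core for ODE-penalized spline fitting (parameter cascading)
// and the genotype-mixture likelihood.
//
// Structural parameter ordering within a genotype column:
//   alpha_L beta_L gamma_L alpha_S beta_S alpha_R beta_R gamma_R
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double W_FLOOR = 1e-8;

// RHS f(mu; theta), Jacobian wrt mu, and optionally derivatives wrt theta.
struct RhsEval {
  vec f = vec(3);
  mat dfdmu = mat(3, 3);       // row k: df_k / d(mu_L, mu_S, mu_R)
  mat dfdth = mat(3, 8);       // row k: df_k / d theta_p
  vec d2_W = vec(3);           // d/dW of (df_k/dW) common factor, see below
};

// For trait k with (a, b) = (alpha, beta):
//   f_k = a W^b - g mu_k (g = 0 for stem)
//   df_k/dmu_m = a b W^(b-1) - g [m == k]
//   d2f_k/dmu dmu = a b (b-1) W^(b-2)  (every entry)
static inline void rhs_eval(const vec& th, double muL, double muS,
                            double muR, RhsEval& e, bool wants_theta) {
  double W = muL + muS + muR;
  bool clamped = W < W_FLOOR;
  if (clamped) W = W_FLOOR;
  double lw = std::log(W);
  double aL = th(0), bL = th(1), gL = th(2);
  double aS = th(3), bS = th(4);
  double aR = th(5), bR = th(6), gR = th(7);
  double WbL = std::exp(bL * lw), WbS = std::exp(bS * lw),
         WbR = std::exp(bR * lw);
  e.f(0) = aL * WbL - gL * muL;
  e.f(1) = aS * WbS;
  e.f(2) = aR * WbR - gR * muR;
  double cL = clamped ? 0.0 : aL * bL * WbL / W;
  double cS = clamped ? 0.0 : aS * bS * WbS / W;
  double cR = clamped ? 0.0 : aR * bR * WbR / W;
  e.dfdmu(0, 0) = cL - gL; e.dfdmu(0, 1) = cL; e.dfdmu(0, 2) = cL;
  e.dfdmu(1, 0) = cS;      e.dfdmu(1, 1) = cS; e.dfdmu(1, 2) = cS;
  e.dfdmu(2, 0) = cR;      e.dfdmu(2, 1) = cR; e.dfdmu(2, 2) = cR - gR;
  e.d2_W(0) = clamped ? 0.0 : aL * bL * (bL - 1.0) * WbL / (W * W);
  e.d2_W(1) = clamped ? 0.0 : aS * bS * (bS - 1.0) * WbS / (W * W);
  e.d2_W(2) = clamped ? 0.0 : aR * bR * (bR - 1.0) * WbR / (W * W);
  if (wants_theta) {
    e.dfdth.zeros();
    e.dfdth(0, 0) = WbL;            // d f_L / d alpha_L
    e.dfdth(0, 1) = aL * WbL * lw;  // d f_L / d beta_L
    e.dfdth(0, 2) = -muL;           // d f_L / d gamma_L
    e.dfdth(1, 3) = WbS;
    e.dfdth(1, 4) = aS * WbS * lw;
    e.dfdth(2, 5) = WbR;
    e.dfdth(2, 6) = aR * WbR * lw;
    e.dfdth(2, 7) = -muR;
  }
}

// Penalized criterion for one genotype block (0.5 * sum of squares form).
// c is length 3R ordered (leaf, stem, root).
static double block_objective(const vec& c, const mat& Phi, const mat& PhiQ,
                              const mat& dPhiQ, const vec& wq,
                              const vec& At, const mat& Ybar,
                              const vec& sigma2, const vec& theta,
                              double lambda, vec& r) {
  const uword T = Phi.n_rows, Q = PhiQ.n_rows, R = Phi.n_cols;
  uword idx = 0;
  RhsEval e;
  for (uword k = 0; k < 3; ++k) {
    vec muk = Phi * c.subvec(k * R, (k + 1) * R - 1);
    for (uword t = 0; t < T; ++t) {
      double wd = std::sqrt(std::max(At(t), 0.0) / sigma2(k));
      r(idx++) = wd * (muk(t) - Ybar(k, t));
    }
  }
  vec muL = PhiQ * c.subvec(0, R - 1);
  vec muS = PhiQ * c.subvec(R, 2 * R - 1);
  vec muR = PhiQ * c.subvec(2 * R, 3 * R - 1);
  vec dL = dPhiQ * c.subvec(0, R - 1);
  vec dS = dPhiQ * c.subvec(R, 2 * R - 1);
  vec dR = dPhiQ * c.subvec(2 * R, 3 * R - 1);
  for (uword q = 0; q < Q; ++q) {
    rhs_eval(theta, muL(q), muS(q), muR(q), e, false);
    double wp = std::sqrt(lambda * wq(q));
    r(idx++) = wp * (dL(q) - e.f(0));
    r(idx++) = wp * (dS(q) - e.f(1));
    r(idx++) = wp * (dR(q) - e.f(2));
  }
  if (!r.is_finite()) return datum::inf;
  return 0.5 * dot(r, r);
}

// Gauss-Newton minimization of the block criterion; warm-startable.
static double block_gauss_newton(vec& c, const mat& Phi, const mat& PhiQ,
                                 const mat& dPhiQ, const vec& wq,
                                 const vec& At, const mat& Ybar,
                                 const vec& sigma2, const vec& theta,
                                 double lambda, int maxit, double tol,
                                 double& gnorm, int& iters) {
  const uword T = Phi.n_rows, Q = PhiQ.n_rows, R = Phi.n_cols;
  const uword nr = 3 * T + 3 * Q, nc = 3 * R;
  vec r(nr), rtry(nr);
  mat J(nr, nc);
  double obj = block_objective(c, Phi, PhiQ, dPhiQ, wq, At, Ybar, sigma2,
                               theta, lambda, r);
  if (!std::isfinite(obj)) {  // recover from an unusable warm start
    c.zeros();
    obj = block_objective(c, Phi, PhiQ, dPhiQ, wq, At, Ybar, sigma2,
                          theta, lambda, r);
  }
  RhsEval e;
  iters = 0;
  gnorm = datum::inf;
  // static data rows of the Jacobian (rows 0 .. 3T-1)
  J.zeros();
  for (uword k = 0; k < 3; ++k) {
    for (uword t = 0; t < T; ++t) {
      double wd = std::sqrt(std::max(At(t), 0.0) / sigma2(k));
      J(k * T + t, span(k * R, (k + 1) * R - 1)) = wd * Phi.row(t);
    }
  }
  vec wp = sqrt(lambda * wq);
  for (int it = 0; it < maxit; ++it) {
    vec muL = PhiQ * c.subvec(0, R - 1);
    vec muS = PhiQ * c.subvec(R, 2 * R - 1);
    vec muR = PhiQ * c.subvec(2 * R, 3 * R - 1);
    mat dmu(Q, 9);  // columns: dfdmu(k, k2) in k-major order
    for (uword q = 0; q < Q; ++q) {
      rhs_eval(theta, muL(q), muS(q), muR(q), e, false);
      for (uword k = 0; k < 3; ++k) {
        for (uword k2 = 0; k2 < 3; ++k2) dmu(q, 3 * k + k2) = e.dfdmu(k, k2);
      }
    }
    // penalty rows, blocked: row block k (rows 3T + k*Q ..) =
    //   wp .* (dPhiQ [block k] - sum_k2 dfdmu(k,k2) .* PhiQ [block k2])
    for (uword k = 0; k < 3; ++k) {
      for (uword k2 = 0; k2 < 3; ++k2) {
        mat blk = PhiQ.each_col() % (-wp % dmu.col(3 * k + k2));
        if (k == k2) blk += dPhiQ.each_col() % wp;
        J(span(3 * T + k * Q, 3 * T + (k + 1) * Q - 1),
          span(k2 * R, (k2 + 1) * R - 1)) = blk;
      }
    }
    // reorder penalty residuals to match the blocked row order
    vec rblk = r;
    for (uword q = 0; q < Q; ++q) {
      for (uword k = 0; k < 3; ++k) {
        rblk(3 * T + k * Q + q) = r(3 * T + 3 * q + k);
      }
    }
    vec g = J.t() * rblk;
    gnorm = norm(g, "inf");
    if (gnorm < tol) break;
    mat H = J.t() * J;
    H.diag() += 1e-10 * (1.0 + trace(H) / nc);
    vec step;
    bool ok = solve(step, H, -g,
                    solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) {
      H.diag() += 1e-6 * (1.0 + trace(H) / nc);
      if (!solve(step, H, -g, solve_opts::no_approx))
        break;
    }
    double alpha = 1.0, newobj = obj;
    bool accepted = false;
    for (int ls = 0; ls < 14; ++ls) {
      vec ctry = c + alpha * step;
      newobj = block_objective(ctry, Phi, PhiQ, dPhiQ, wq, At, Ybar, sigma2,
                               theta, lambda, rtry);
      if (std::isfinite(newobj) && newobj <= obj - 1e-14) {
        c = ctry; r = rtry; obj = newobj; accepted = true; break;
      }
      alpha *= 0.5;
    }
    ++iters;
    if (!accepted) break;
  }
  return obj;
}

// [[Rcpp::export]]
Rcpp::List cpp_inner_fit(const arma::mat& Phi, const arma::mat& PhiQ,
                         const arma::mat& dPhiQ, const arma::vec& wq,
                         const arma::mat& A, const arma::cube& Ybar,
                         const arma::vec& sigma2, const arma::mat& Theta,
                         double lambda, arma::mat C0, int maxit = 100,
                         double tol = 1e-8) {
  const uword J = Theta.n_cols;
  vec obj(J), gnorm(J);
  Rcpp::IntegerVector iters(J);
  bool conv = true;
  for (uword j = 0; j < J; ++j) {
    vec c = C0.col(j);
    int it = 0; double gn = 0.0;
    obj(j) = block_gauss_newton(c, Phi, PhiQ, dPhiQ, wq, A.col(j),
                                Ybar.slice(j), sigma2, Theta.col(j), lambda,
                                maxit, tol, gn, it);
    C0.col(j) = c;
    gnorm(j) = gn; iters[j] = it;
    if (!std::isfinite(obj(j)) ||
        gn >= std::max(tol, 1e-4 * (1.0 + std::abs(obj(j))))) conv = false;
  }
  return Rcpp::List::create(Rcpp::Named("C") = C0,
                            Rcpp::Named("obj") = obj,
                            Rcpp::Named("gnorm") = gnorm,
                            Rcpp::Named("iters") = iters,
                            Rcpp::Named("converged") = conv);
}

// Mixture log-likelihood over RILs with diagonal trait-specific variances.
// Y: cube (n x T x 3), NaN = unobserved. mu: cube (T x 3 x J).
// omega: n x J prior conditional genotype probabilities.
// Returns the log-likelihood, posterior weights, posterior-weighted
// residual sums of squares per trait (for the variance EM update), the
// observation counts, and the posterior-weighted residuals at each
// (time, trait, genotype) (the derivative of lnL wrt the mean curves,
// scaled by sigma^2).
// [[Rcpp::export]]
Rcpp::List cpp_mixture_loglik(const arma::cube& Y, const arma::mat& omega,
                              const arma::cube& mu, const arma::vec& sigma2) {
  const uword n = Y.n_rows, T = Y.n_cols, J = mu.n_slices;
  const double log2pi = std::log(2.0 * M_PI);
  mat q(n, J, fill::zeros);
  cube rss(n, J, 3, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    for (uword j = 0; j < J; ++j) {
      double lq = 0.0;
      for (uword k = 0; k < 3; ++k) {
        for (uword t = 0; t < T; ++t) {
          double y = Y(i, t, k);
          if (!std::isfinite(y)) continue;
          double e = y - mu(t, k, j);
          rss(i, j, k) += e * e;
          lq += -0.5 * (e * e / sigma2(k) + std::log(sigma2(k)) + log2pi);
        }
      }
      q(i, j) = lq;
    }
  }
  vec nobs(3, fill::zeros);
  for (uword k = 0; k < 3; ++k) {
    for (uword t = 0; t < T; ++t) {
      for (uword i = 0; i < n; ++i) {
        if (std::isfinite(Y(i, t, k))) nobs(k) += 1.0;
      }
    }
  }
  mat post(n, J, fill::zeros);
  double lnL = 0.0;
  for (uword i = 0; i < n; ++i) {
    double m = -datum::inf;
    for (uword j = 0; j < J; ++j) {
      if (omega(i, j) > 0.0) m = std::max(m, std::log(omega(i, j)) + q(i, j));
    }
    double s = 0.0;
    for (uword j = 0; j < J; ++j) {
      if (omega(i, j) > 0.0) {
        post(i, j) = std::exp(std::log(omega(i, j)) + q(i, j) - m);
        s += post(i, j);
      }
    }
    lnL += m + std::log(s);
    post.row(i) /= s;
  }
  vec ss(3, fill::zeros);
  // dlnL/dmu(t, k, j) = sum_i post(i,j) (y_ikt - mu_tkj) / sigma2_k
  cube dmu(T, 3, J, fill::zeros);
  for (uword k = 0; k < 3; ++k) {
    for (uword j = 0; j < J; ++j) {
      for (uword i = 0; i < n; ++i) {
        ss(k) += post(i, j) * rss(i, j, k);
        for (uword t = 0; t < T; ++t) {
          double y = Y(i, t, k);
          if (!std::isfinite(y)) continue;
          dmu(t, k, j) += post(i, j) * (y - mu(t, k, j)) / sigma2(k);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = lnL,
                            Rcpp::Named("posterior") = post,
                            Rcpp::Named("ss") = ss,
                            Rcpp::Named("nobs") = nobs,
                            Rcpp::Named("dmu") = dmu);
}

// Gradient of the profiled mixture log-likelihood wrt Theta by the
// implicit function theorem: with c_j(theta_j) minimizing the inner
// criterion U_j, dc_j/dtheta = -H_j^{-1} U_ctheta and
// dlnL/dtheta_j = (dlnL/dc_j)' dc_j/dtheta.
// H_j is the exact inner Hessian at the optimum; U_ctheta the mixed
// second derivative. Must be called at a converged inner fit (C).
// [[Rcpp::export]]
Rcpp::List cpp_profile_grad(const arma::mat& Phi, const arma::mat& PhiQ,
                            const arma::mat& dPhiQ, const arma::vec& wq,
                            const arma::mat& A, const arma::cube& Ybar,
                            const arma::vec& sigma2, const arma::mat& Theta,
                            double lambda, const arma::mat& C,
                            const arma::cube& dmu_lnL) {
  const uword T = Phi.n_rows, Q = PhiQ.n_rows, R = Phi.n_cols;
  const uword J = Theta.n_cols, nc = 3 * R;
  mat grad(8, J, fill::zeros);
  RhsEval e;
  const vec w = 2.0 * lambda * wq;
  const vec sw = sqrt(w);
  for (uword j = 0; j < J; ++j) {
    const vec th = Theta.col(j);
    const vec c = C.col(j);
    mat Cm(const_cast<double*>(c.memptr()), R, 3, false, true);
    mat muQ = PhiQ * Cm;    // Q x 3
    mat dmuQ = dPhiQ * Cm;  // Q x 3
    // pointwise RHS quantities
    mat f(Q, 3), dmu(Q, 9), d2W(Q, 3), Fth(Q, 8, fill::zeros);
    vec lwv(Q);
    for (uword q = 0; q < Q; ++q) {
      rhs_eval(th, muQ(q, 0), muQ(q, 1), muQ(q, 2), e, true);
      for (uword k = 0; k < 3; ++k) {
        f(q, k) = e.f(k);
        d2W(q, k) = e.d2_W(k);
        for (uword k2 = 0; k2 < 3; ++k2) dmu(q, 3 * k + k2) = e.dfdmu(k, k2);
      }
      double W = std::max(muQ(q, 0) + muQ(q, 1) + muQ(q, 2), W_FLOOR);
      lwv(q) = std::log(W);
      // dfdth, stored row-wise per trait via the sparse pattern below
      Fth(q, 0) = e.dfdth(0, 0); Fth(q, 1) = e.dfdth(0, 1);
      Fth(q, 2) = e.dfdth(0, 2);
      Fth(q, 3) = e.dfdth(1, 3); Fth(q, 4) = e.dfdth(1, 4);
      Fth(q, 5) = e.dfdth(2, 5); Fth(q, 6) = e.dfdth(2, 6);
      Fth(q, 7) = e.dfdth(2, 7);
    }
    mat res = dmuQ - f;  // Q x 3
    // sqrt(w)-scaled penalty Jacobian, rows blocked by trait k
    mat Gs(3 * Q, nc);
    for (uword k = 0; k < 3; ++k) {
      for (uword k2 = 0; k2 < 3; ++k2) {
        mat blk = PhiQ.each_col() % (-sw % dmu.col(3 * k + k2));
        if (k == k2) blk += dPhiQ.each_col() % sw;
        Gs(span(k * Q, (k + 1) * Q - 1), span(k2 * R, (k2 + 1) * R - 1)) = blk;
      }
    }
    mat H = Gs.t() * Gs;
    // data part of the Hessian: 2 * Phi' D Phi per trait block
    for (uword k = 0; k < 3; ++k) {
      vec d = 2.0 * clamp(A.col(j), 0.0, datum::inf) / sigma2(k);
      H(span(k * R, (k + 1) * R - 1), span(k * R, (k + 1) * R - 1)) +=
        Phi.t() * (Phi.each_col() % d);
    }
    // curvature of f: d2 f_k / dmu dmu' = d2_W(k) in every entry (the
    // -gamma mu_k terms are linear and vanish); accumulated over k with
    // weight -res_k, identical in all 9 blocks
    vec curv = -(res.col(0) % d2W.col(0) + res.col(1) % d2W.col(1) +
                 res.col(2) % d2W.col(2));
    mat M = PhiQ.t() * (PhiQ.each_col() % (w % curv));
    for (uword k = 0; k < 3; ++k) {
      for (uword k2 = 0; k2 < 3; ++k2) {
        H(span(k * R, (k + 1) * R - 1), span(k2 * R, (k2 + 1) * R - 1)) += M;
      }
    }
    // mixed derivative U_ctheta = sum_q w [ G_q' (-dfdth_q) ]
    //   + residual-times-mixed-curvature terms.
    // First part: stack dfdth rows to match Gs' blocked row order.
    mat Fb(3 * Q, 8, fill::zeros);
    Fb(span(0, Q - 1), span(0, 2)) = Fth.cols(0, 2);
    Fb(span(Q, 2 * Q - 1), span(3, 4)) = Fth.cols(3, 4);
    Fb(span(2 * Q, 3 * Q - 1), span(5, 7)) = Fth.cols(5, 7);
    mat Uct = -Gs.t() * (Fb.each_col() % repmat(sw, 3, 1));
    // W-channel mixed curvature: d2f_k/dmu_m dalpha_k = b W^(b-1) and
    // d2f_k/dmu_m dbeta_k = a W^(b-1)(1 + b lnW) for every m; plus
    // d2f_k/dmu_k dgamma_k = -1 (own block only).
    vec WbL1 = exp((th(1) - 1.0) * lwv), WbS1 = exp((th(4) - 1.0) * lwv),
        WbR1 = exp((th(6) - 1.0) * lwv);
    struct MixedSpec { uword k; uword p; const vec* valW; };
    vec vaL = th(1) * WbL1, vbL = th(0) * (WbL1 % (1.0 + th(1) * lwv));
    vec vaS = th(4) * WbS1, vbS = th(3) * (WbS1 % (1.0 + th(4) * lwv));
    vec vaR = th(6) * WbR1, vbR = th(5) * (WbR1 % (1.0 + th(6) * lwv));
    MixedSpec specs[6] = {{0, 0, &vaL}, {0, 1, &vbL}, {1, 3, &vaS},
                          {1, 4, &vbS}, {2, 5, &vaR}, {2, 6, &vbR}};
    for (const MixedSpec& s : specs) {
      vec u = PhiQ.t() * (w % (-res.col(s.k)) % (*s.valW));
      for (uword k2 = 0; k2 < 3; ++k2) {
        Uct(span(k2 * R, (k2 + 1) * R - 1), s.p) += u;
      }
    }
    Uct(span(0, R - 1), 2) += PhiQ.t() * (w % res.col(0));
    Uct(span(2 * R, 3 * R - 1), 7) += PhiQ.t() * (w % res.col(2));
    // dlnL/dc_j: per trait block Phi' dmu_lnL(:,k,j)
    vec glc(nc);
    for (uword k = 0; k < 3; ++k) {
      glc.subvec(k * R, (k + 1) * R - 1) = Phi.t() * dmu_lnL.slice(j).col(k);
    }
    // dc/dtheta = -H^{-1} Uct ;  grad_j = (dc/dtheta)' glc
    mat Hs = H;
    Hs.diag() += 1e-10 * (1.0 + trace(H) / nc);
    mat X;
    if (!solve(X, Hs, Uct,
               solve_opts::likely_sympd + solve_opts::no_approx)) {
      Hs.diag() += 1e-6 * (1.0 + trace(H) / nc);
      if (!solve(X, Hs, Uct, solve_opts::no_approx)) {
        X.zeros(nc, 8);
      }
    }
    grad.col(j) = -X.t() * glc;
  }
  return Rcpp::List::create(Rcpp::Named("grad") = grad);
}
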