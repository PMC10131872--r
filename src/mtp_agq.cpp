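// Marginalized two-part likelihood with correlated random intercepts,
// integrated by (adaptive) Gauss-Hermite product quadrature.
//
// Model, conditional on subject effects b = (a, d):
//   P(Y > 0)        = pi   = logistic(x1'alpha + a)
//   E(Y | b)        = nu   = exp(x2'beta + d)        (overall mean, zeros in)
//   Y | Y > 0       ~ Gamma(shape kappa, mean mu = nu / max(pi, PI_FLOOR))
//   (a, d)          ~ N2(0, Sigma(sigma_a, sigma_d, rho))
//
// The quadrature substitutes b = m + sqrt(2) * A * t with A A' equal to a
// scale matrix (prior Cholesky for plain quadrature; inverse-curvature
// factor at the per-subject posterior mode for adaptive quadrature), so a
// single code path serves both modes. Gradients are exact derivatives of
// the fixed-node approximation; the fitting driver re-centres nodes
// between optimizer cycles.
//
// Hot-path layout: quantities constant across quadrature nodes (log y,
// exp(-eta2), the kappa terms of the gamma normalizing constant) are
// precomputed per observation, leaving one exp and one log1p per
// observation-node pair.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double PI_FLOOR = 1e-6;
static const double LOG_PI_FLOOR = std::log(PI_FLOOR);

struct ObsEval {
  double ll, g1, g2, gk, h11, h12, h22;
  bool floored;
};

// stable logistic pieces: pi = plogis(x), logpi = log(pi), one exp + log1p
static inline void logistic_parts(double x, double &pi, double &logpi) {
  if (x > 0) {
    const double q = std::exp(-x);
    pi = 1.0 / (1.0 + q);
    logpi = -std::log1p(q);
  } else {
    const double e = std::exp(x);
    pi = e / (1.0 + e);
    logpi = x - std::log1p(e);
  }
}

// log-density of one observation and derivatives w.r.t. the two linear
// predictors and kappa (natural scale).
//   y > 0 path inputs: logy/cj/E2 precomputed per observation, emd =
//   exp(-d) per node, eta2t = x2'beta + d.
static inline void obs_eval(double y, double logy, double cj, double yE2,
                            double eta1t, double eta2t, double emd,
                            double kappa, double logkap, double dgk,
                            bool second, ObsEval &o) {
  double pi, logpi;
  logistic_parts(eta1t, pi, logpi);
  const double omp = 1.0 - pi;
  o.floored = false;
  if (y == 0.0) {
    o.ll = logpi - eta1t;        // log(1 - pi) = logpi - eta1t (logit ident.)
    o.g1 = -pi;
    o.g2 = 0.0; o.gk = 0.0;
    if (second) { o.h11 = -pi * omp; o.h12 = 0.0; o.h22 = 0.0; }
    return;
  }
  double piu = pi, logpiu = logpi;
  if (pi < PI_FLOOR) { piu = PI_FLOOR; logpiu = LOG_PI_FLOOR; o.floored = true; }
  double w = yE2 * piu * emd;                   // y / mu
  if (w > 1e300) w = 1e300;                     // keep the integrand finite
  o.ll = logpi + kappa * logpiu + cj - kappa * eta2t - kappa * w;
  if (o.floored) {
    o.g1 = omp;                                 // only d log(pi) survives
    if (second) o.h11 = -pi * omp;
  } else {
    o.g1 = omp * (1.0 + kappa) - kappa * w * omp;
    if (second) o.h11 = -pi * omp * (1.0 + kappa)
                        - kappa * w * omp * (1.0 - 2.0 * pi);
  }
  o.g2 = -kappa + kappa * w;
  o.gk = logkap + 1.0 - (eta2t - logpiu) - dgk + logy - w;
  if (second) {
    o.h12 = o.floored ? 0.0 : kappa * w * omp;
    o.h22 = -kappa * w;
  }
}

// Laplace mode and curvature factor for one subject: maximizes
// sum_j ll_j(b) - b' Sigma^{-1} b / 2 by damped Newton, then factors the
// negative inverse Hessian as A A'.
static void subject_mode(const double *eta1, const double *eta2,
                         const double *y, const double *logy,
                         const double *cj, const double *yE2, int n,
                         double kappa, double logkap, double dgk,
                         const arma::mat &Sinv, arma::vec &b, arma::mat &A) {
  ObsEval o;
  arma::vec g(2), step(2);
  arma::mat H(2, 2);
  auto objective = [&](const arma::vec &bb) {
    const double emd = std::exp(-bb[1]);
    double s = -0.5 * (Sinv(0, 0) * bb[0] * bb[0] +
                       2.0 * Sinv(0, 1) * bb[0] * bb[1] +
                       Sinv(1, 1) * bb[1] * bb[1]);
    for (int j = 0; j < n; ++j) {
      obs_eval(y[j], logy[j], cj[j], yE2[j], eta1[j] + bb[0],
               eta2[j] + bb[1], emd, kappa, logkap, dgk, false, o);
      s += o.ll;
    }
    return s;
  };
  double h_cur = objective(b);
  for (int it = 0; it < 40; ++it) {
    g.zeros(); H.zeros();
    const double emd = std::exp(-b[1]);
    for (int j = 0; j < n; ++j) {
      obs_eval(y[j], logy[j], cj[j], yE2[j], eta1[j] + b[0],
               eta2[j] + b[1], emd, kappa, logkap, dgk, true, o);
      g[0] += o.g1; g[1] += o.g2;
      H(0, 0) += o.h11; H(0, 1) += o.h12; H(1, 1) += o.h22;
    }
    H(1, 0) = H(0, 1);
    g[0] -= Sinv(0, 0) * b[0] + Sinv(0, 1) * b[1];
    g[1] -= Sinv(0, 1) * b[0] + Sinv(1, 1) * b[1];
    H -= Sinv;
    if (std::max(std::abs(g[0]), std::abs(g[1])) < 1e-9) break;
    arma::mat M = -H;
    double lam = 0.0;
    while (M(0, 0) <= 0 || M(0, 0) * M(1, 1) - M(0, 1) * M(1, 0) <= 0) {
      lam = (lam == 0.0) ? 1e-4 : lam * 10.0;
      M = -H + lam * arma::eye(2, 2);
      if (lam > 1e8) break;
    }
    step = arma::solve(M, g, arma::solve_opts::likely_sympd);
    double t = 1.0;
    bool improved = false;
    double h_new = h_cur;
    for (int ls = 0; ls < 14; ++ls) {
      arma::vec bt = b + t * step;
      h_new = objective(bt);
      if (std::isfinite(h_new) && h_new >= h_cur - 1e-12) {
        b = bt; improved = (h_new > h_cur + 1e-12); h_cur = h_new; break;
      }
      t *= 0.5;
    }
    if (!improved) break;
  }
  // curvature factor at the mode
  H.zeros();
  const double emd = std::exp(-b[1]);
  for (int j = 0; j < n; ++j) {
    obs_eval(y[j], logy[j], cj[j], yE2[j], eta1[j] + b[0],
             eta2[j] + b[1], emd, kappa, logkap, dgk, true, o);
    H(0, 0) += o.h11; H(0, 1) += o.h12; H(1, 1) += o.h22;
  }
  H(1, 0) = H(0, 1);
  H -= Sinv;
  arma::mat M = -H;
  double lam = 0.0;
  while (M(0, 0) <= 0 || M(0, 0) * M(1, 1) - M(0, 1) * M(1, 0) <= 1e-12) {
    lam = (lam == 0.0) ? 1e-6 : lam * 10.0;
    M = -H + lam * arma::eye(2, 2);
    if (lam > 1e10) { M = Sinv; break; }
  }
  arma::mat R = arma::chol(M);          // upper: M = R' R
  A = arma::inv(arma::trimatu(R));      // A A' = M^{-1}
}

// shared precomputation for both entry points
struct Workspace {
  arma::vec eta1, eta2, logy, cj, yE2;
  double kappa, logkap, lgk, dgk, sa, sd, rho, c;
};

static void fill_workspace(const arma::mat &X1, const arma::mat &X2,
                           const arma::vec &y, const arma::vec &alpha,
                           const arma::vec &beta, double logkappa,
                           double logsa, double logsd, double zrho,
                           Workspace &W) {
  W.kappa = std::exp(logkappa);
  W.logkap = logkappa;
  W.lgk = std::lgamma(W.kappa);
  W.dgk = R::digamma(W.kappa);
  W.sa = std::exp(logsa); W.sd = std::exp(logsd);
  W.rho = std::tanh(zrho);
  W.c = 1.0 - W.rho * W.rho;
  W.eta1 = X1 * alpha;
  W.eta2 = X2 * beta;
  const arma::uword n = y.n_elem;
  W.logy.zeros(n); W.cj.zeros(n); W.yE2.zeros(n);
  const double kl = W.kappa * W.logkap - W.lgk;
  for (arma::uword j = 0; j < n; ++j) {
    if (y[j] > 0) {
      W.logy[j] = std::log(y[j]);
      W.cj[j] = kl + (W.kappa - 1.0) * W.logy[j];
      double e2 = W.eta2[j];
      // exp(-eta2) can overflow for extreme trial parameters; the w clamp
      // in obs_eval keeps the likelihood finite either way
      W.yE2[j] = y[j] * std::exp(e2 < -690.0 ? 690.0 : -e2);
    }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_mtp_modes(const arma::mat &X1, const arma::mat &X2,
                         const arma::vec &y, const arma::ivec &sidx,
                         const arma::vec &alpha, const arma::vec &beta,
                         double logkappa, double logsa, double logsd,
                         double zrho, const arma::mat &start_modes) {
  const int ns = sidx.n_elem - 1;
  Workspace W;
  fill_workspace(X1, X2, y, alpha, beta, logkappa, logsa, logsd, zrho, W);
  arma::mat Sigma = {{W.sa * W.sa, W.rho * W.sa * W.sd},
                     {W.rho * W.sa * W.sd, W.sd * W.sd}};
  arma::mat Sinv = arma::inv_sympd(Sigma);
  arma::mat modes(ns, 2), scales(ns, 4);
  const bool warm = start_modes.n_rows == (arma::uword)ns;
  for (int i = 0; i < ns; ++i) {
    const int a0 = sidx[i];
    const int n_i = sidx[i + 1] - a0;
    arma::vec b(2, arma::fill::zeros);
    if (warm) { b[0] = start_modes(i, 0); b[1] = start_modes(i, 1); }
    arma::mat A(2, 2);
    subject_mode(W.eta1.memptr() + a0, W.eta2.memptr() + a0,
                 y.memptr() + a0, W.logy.memptr() + a0,
                 W.cj.memptr() + a0, W.yE2.memptr() + a0, n_i,
                 W.kappa, W.logkap, W.dgk, Sinv, b, A);
    modes(i, 0) = b[0]; modes(i, 1) = b[1];
    scales(i, 0) = A(0, 0); scales(i, 1) = A(0, 1);
    scales(i, 2) = A(1, 0); scales(i, 3) = A(1, 1);
  }
  return Rcpp::List::create(Rcpp::Named("modes") = modes,
                            Rcpp::Named("scales") = scales);
}

// [[Rcpp::export]]
Rcpp::List cpp_mtp_loglik(const arma::mat &X1, const arma::mat &X2,
                          const arma::vec &y, const arma::ivec &sidx,
                          const arma::vec &alpha, const arma::vec &beta,
                          double logkappa, double logsa, double logsd,
                          double zrho, const arma::mat &Tnodes,
                          const arma::vec &logw, const arma::mat &modes,
                          const arma::mat &scales, bool want_grad) {
  const int ns = sidx.n_elem - 1;
  const int K = Tnodes.n_rows;
  const int p1 = alpha.n_elem, p2 = beta.n_elem;
  Workspace W;
  fill_workspace(X1, X2, y, alpha, beta, logkappa, logsa, logsd, zrho, W);
  const double lphi_const = -std::log(2.0 * M_PI) - logsa - logsd
                            - 0.5 * std::log(W.c);
  const double sqrt2 = std::sqrt(2.0);

  arma::vec subj_ll(ns);
  arma::vec grad(want_grad ? p1 + p2 + 4 : 0, arma::fill::zeros);
  arma::vec tsq(K);
  for (int k = 0; k < K; ++k)
    tsq[k] = Tnodes(k, 0) * Tnodes(k, 0) + Tnodes(k, 1) * Tnodes(k, 1);

  int maxn = 0;
  for (int i = 0; i < ns; ++i)
    maxn = std::max(maxn, sidx[i + 1] - sidx[i]);
  arma::mat G1(maxn, K), G2(maxn, K);
  arma::vec val(K), gkk(K), gsa(K), gsd(K), gzr(K), pk(K);
  ObsEval o;
  long n_floor = 0;
  double total = 0.0;

  for (int i = 0; i < ns; ++i) {
    const int a0 = sidx[i], n_i = sidx[i + 1] - a0;
    const double m0 = modes(i, 0), m1 = modes(i, 1);
    const double A00 = scales(i, 0), A01 = scales(i, 1);
    const double A10 = scales(i, 2), A11 = scales(i, 3);
    const double absdet = std::abs(A00 * A11 - A01 * A10);
    for (int k = 0; k < K; ++k) {
      const double t0 = Tnodes(k, 0), t1 = Tnodes(k, 1);
      const double b0 = m0 + sqrt2 * (A00 * t0 + A01 * t1);
      const double b1 = m1 + sqrt2 * (A10 * t0 + A11 * t1);
      const double emd = std::exp(-b1);
      const double u = b0 / W.sa, v = b1 / W.sd;
      const double Q = (u * u - 2.0 * W.rho * u * v + v * v) / W.c;
      double s = lphi_const - 0.5 * Q;
      double sk = 0.0;
      for (int j = 0; j < n_i; ++j) {
        const int jj = a0 + j;
        obs_eval(y[jj], W.logy[jj], W.cj[jj], W.yE2[jj],
                 W.eta1[jj] + b0, W.eta2[jj] + b1, emd,
                 W.kappa, W.logkap, W.dgk, false, o);
        s += o.ll;
        if (o.floored) ++n_floor;
        if (want_grad) {
          G1(j, k) = o.g1; G2(j, k) = o.g2; sk += o.gk;
        }
      }
      val[k] = logw[k] + tsq[k] + s;
      if (want_grad) {
        gkk[k] = sk;
        gsa[k] = -1.0 + (u * u - W.rho * u * v) / W.c;
        gsd[k] = -1.0 + (v * v - W.rho * u * v) / W.c;
        gzr[k] = W.rho + u * v - W.rho * Q;
      }
    }
    const double vmax = val.max();
    if (!std::isfinite(vmax))
      Rcpp::stop("non-finite integrand for subject %d", i + 1);
    double sumexp = 0.0;
    for (int k = 0; k < K; ++k) sumexp += std::exp(val[k] - vmax);
    const double ll_i = std::log(2.0 * absdet) + vmax + std::log(sumexp);
    subj_ll[i] = ll_i;
    total += ll_i;
    if (want_grad) {
      for (int k = 0; k < K; ++k) pk[k] = std::exp(val[k] - vmax) / sumexp;
      // coefficient gradients: X' (posterior-weighted observation scores)
      for (int j = 0; j < n_i; ++j) {
        double r1 = 0.0, r2 = 0.0;
        for (int k = 0; k < K; ++k) {
          r1 += pk[k] * G1(j, k);
          r2 += pk[k] * G2(j, k);
        }
        const int jj = a0 + j;
        for (int cix = 0; cix < p1; ++cix)
          grad[cix] += X1(jj, cix) * r1;
        for (int cix = 0; cix < p2; ++cix)
          grad[p1 + cix] += X2(jj, cix) * r2;
      }
      double gk_i = 0.0, gsa_i = 0.0, gsd_i = 0.0, gzr_i = 0.0;
      for (int k = 0; k < K; ++k) {
        gk_i += pk[k] * gkk[k];
        gsa_i += pk[k] * gsa[k];
        gsd_i += pk[k] * gsd[k];
        gzr_i += pk[k] * gzr[k];
      }
      grad[p1 + p2] += W.kappa * gk_i;      // d/d log kappa
      grad[p1 + p2 + 1] += gsa_i;
      grad[p1 + p2 + 2] += gsd_i;
      grad[p1 + p2 + 3] += gzr_i;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("loglik") = total, Rcpp::Named("grad") = grad,
      Rcpp::Named("subject_ll") = subj_ll,
      Rcpp::Named("n_floor") = (double)n_floor);
}
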