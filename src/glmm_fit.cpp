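// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Doubly iterative pseudo-response GLMM fit for univariate families with a
// low-rank (marker-factor) kinship K = P P'. Mirrors the R reference path:
// inner loop 1 relinearizes at fixed variance components, inner loop 2 runs
// profiled REML in the basis that diagonalizes W^{1/2} K W^{1/2} (thin, via
// the m x m Gram matrix), the outer loop alternates until the variance
// components converge. Family codes: 1 binary, 2 binomial, 3 poisson.

namespace {

constexpr double MU_EPS = 1e-8;

struct Pseudo {
  arma::vec p;
  arma::vec w;
};

Pseudo pseudo_uni(const arma::vec& u, const arma::vec& eta, int fam,
                  const arma::vec& trials) {
  arma::vec mu, delta, w;
  if (fam == 3) {
    mu = arma::clamp(arma::exp(eta), MU_EPS, arma::datum::inf);
    delta = mu;
    w = mu;
  } else {
    mu = 1.0 / (1.0 + arma::exp(-eta));
    mu = arma::clamp(mu, MU_EPS, 1.0 - MU_EPS);
    delta = mu % (1.0 - mu);
    w = (fam == 2) ? arma::vec(trials % delta) : delta;
  }
  Pseudo ps;
  ps.p = (u - mu) / delta + eta;
  ps.w = w;
  return ps;
}

struct Setup {
  arma::mat U;   // N x r rotated basis
  arma::vec d;   // r eigenvalues of W^{1/2} K W^{1/2}
  arma::vec s;   // sqrt working weights
  arma::vec ystar, yr, Xty;
  arma::mat Xstar, Xr, XtX;
  double yty, logdetW;
  int N, p;
};

Setup make_setup(const arma::vec& ptil, const arma::mat& X, const arma::mat& P,
                 const arma::vec& w) {
  Setup su;
  su.s = arma::sqrt(w);
  arma::mat SP = P.each_col() % su.s;
  arma::mat G = SP.t() * SP;
  arma::vec ev;
  arma::mat V;
  arma::eig_sym(ev, V, G, "dc");
  ev = arma::clamp(ev, 0.0, arma::datum::inf);
  double cut = ev.max() * 1e-12;
  arma::uvec keep = arma::find(ev > cut);
  su.d = ev(keep);
  arma::mat Vk = V.cols(keep);
  Vk.each_row() /= arma::sqrt(su.d).t();
  su.U = SP * Vk;
  su.ystar = su.s % ptil;
  su.Xstar = X.each_col() % su.s;
  su.yr = su.U.t() * su.ystar;
  su.Xr = su.U.t() * su.Xstar;
  su.XtX = su.Xstar.t() * su.Xstar;
  su.Xty = su.Xstar.t() * su.ystar;
  su.yty = arma::dot(su.ystar, su.ystar);
  su.logdetW = arma::accu(arma::log(w));
  su.N = ptil.n_elem;
  su.p = X.n_cols;
  return su;
}

struct Prof {
  double loglik, sigma_e2;
  arma::vec beta, dv, a, rr;
  arma::mat XtVX;
};

Prof profile(double lambda, const Setup& su) {
  Prof pr;
  pr.dv = lambda * su.d + 1.0;
  pr.a = 1.0 / pr.dv - 1.0;
  pr.XtVX = su.XtX + su.Xr.t() * (su.Xr.each_col() % pr.a);
  arma::vec rhs = su.Xty + su.Xr.t() * (pr.a % su.yr);
  pr.beta = arma::solve(pr.XtVX, rhs, arma::solve_opts::likely_sympd);
  pr.rr = su.yr - su.Xr * pr.beta;
  double rnorm2 = su.yty - 2.0 * arma::dot(pr.beta, su.Xty) +
    arma::dot(pr.beta, su.XtX * pr.beta);
  if (rnorm2 < 0) rnorm2 = 0;
  double q = rnorm2 + arma::dot(pr.a, arma::square(pr.rr));
  pr.sigma_e2 = q / (su.N - su.p);
  double ld_xvx, sign;
  arma::log_det(ld_xvx, sign, pr.XtVX);
  pr.loglik = -0.5 * ((su.N - su.p) * (std::log(pr.sigma_e2) + 1.0) +
                      arma::accu(arma::log(pr.dv)) - su.logdetW + ld_xvx);
  return pr;
}

double score(double lambda, const Setup& su) {
  Prof pr = profile(lambda, su);
  double q = pr.sigma_e2 * (su.N - su.p);
  double dq = -arma::dot(arma::square(pr.rr), su.d / arma::square(pr.dv));
  arma::mat Xs = su.Xr.each_col() % (su.d / arma::square(pr.dv));
  arma::mat T = arma::solve(pr.XtVX, su.Xr.t() * Xs,
                            arma::solve_opts::likely_sympd);
  double tr = -arma::trace(T);
  return -0.5 * ((su.N - su.p) * dq / q + arma::accu(su.d / pr.dv) + tr);
}

// golden-section localization + score-root polish on ln(lambda)
double search_lambda(const Setup& su, double llo, double lhi, double warm) {
  auto obj = [&](double ll) { return profile(std::exp(ll), su).loglik; };
  double a = llo, b = lhi;
  if (std::isfinite(warm)) {
    a = std::max(llo, warm - 2.0);
    b = std::min(lhi, warm + 2.0);
  }
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  for (int pass = 0; pass < 2; ++pass) {
    double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
    double f1 = obj(x1), f2 = obj(x2);
    while (b - a > 1e-3) {
      if (f1 < f2) {
        a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a); f2 = obj(x2);
      } else {
        b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a); f1 = obj(x1);
      }
    }
    // if a warm bracket collapsed onto an edge, redo over the full range
    double mid = 0.5 * (a + b);
    bool edge = (mid - llo < 1e-2 && a > llo + 1e-9) ||
                (lhi - mid < 1e-2 && b < lhi - 1e-9);
    if (!edge || (a <= llo + 1e-9 && b >= lhi - 1e-9)) break;
    a = llo; b = lhi;
  }
  double loglam = 0.5 * (a + b);
  // compare against the bounds (boundary optimum allowed)
  double fm = obj(loglam), flo = obj(llo), fhi = obj(lhi);
  if (flo >= fm && flo >= fhi) return llo;
  if (fhi >= fm && fhi > flo) return lhi;
  // polish interior optimum by bisection on the score
  auto g = [&](double ll) { return score(std::exp(ll), su) * std::exp(ll); };
  double lo = loglam - 0.02, hi = loglam + 0.02;
  for (int grow = 0; grow < 6; ++grow) {
    lo = std::max(lo, llo); hi = std::min(hi, lhi);
    if (g(lo) > 0 && g(hi) < 0) break;
    lo = loglam - (loglam - lo) * 4.0;
    hi = loglam + (hi - loglam) * 4.0;
  }
  if (!(g(lo) > 0 && g(hi) < 0)) return loglam;
  for (int it = 0; it < 100 && hi - lo > 1e-12; ++it) {
    double mid = 0.5 * (lo + hi);
    if (g(mid) > 0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// GLS + BLUP at fixed variance components via the Woodbury identity:
// V = sg P P' + se W^{-1}, V^{-1} b = D b - D P (I/sg + P' D P)^{-1} P' D b
// with D = diag(w/se). Much cheaper than the rotated setup when only a
// fixed-lambda solve is needed (inner loop 1 and the P3D per-marker step).
struct Gls {
  arma::vec beta, gamma;
  arma::mat cov_beta;
};

Gls gls_fixed(const arma::vec& p, const arma::mat& X, const arma::mat& P,
              const arma::vec& w, double sg, double se) {
  arma::vec dinv = w / se;
  arma::mat DiP = P.each_col() % dinv;
  arma::mat Mi;
  bool lowrank = sg > 0;
  if (lowrank) {
    arma::mat M = arma::eye(P.n_cols, P.n_cols) / sg + P.t() * DiP;
    Mi = arma::inv_sympd(M);
  }
  auto vi_mult = [&](const arma::mat& B) -> arma::mat {
    arma::mat DiB = B.each_col() % dinv;
    if (!lowrank) return DiB;
    return DiB - DiP * (Mi * (DiP.t() * B));
  };
  arma::mat Vi_X = vi_mult(X);
  arma::vec Vi_p = vi_mult(p);
  arma::mat XtVX = X.t() * Vi_X;
  Gls out;
  out.cov_beta = arma::inv_sympd(XtVX);
  out.beta = out.cov_beta * (X.t() * Vi_p);
  arma::vec Vi_r = Vi_p - Vi_X * out.beta;
  out.gamma = sg * (P * (P.t() * Vi_r));
  return out;
}

arma::vec clamp_eta(const arma::vec& eta, double clamp, bool* clamped) {
  arma::vec out = arma::clamp(eta, -clamp, clamp);
  if (arma::any(arma::abs(eta) > clamp)) *clamped = true;
  return out;
}

} // namespace

// [[Rcpp::export(name = ".glmm_fit_uni")]]
Rcpp::List glmm_fit_uni(const arma::vec& u, const arma::mat& X,
                        const arma::mat& P, int fam, const arma::vec& trials,
                        const arma::vec& beta0, const arma::vec& gamma0,
                        double sg0, double se0, bool have_vc, bool fix_vc,
                        double tol_i1, double tol_outer, int max_i1,
                        int max_outer, double clampv, double llo, double lhi) {
  const int N = u.n_elem;
  bool clamped = false;
  arma::vec beta = beta0, gamma = gamma0;
  arma::vec eta = clamp_eta(X * beta + gamma, clampv, &clamped);
  int n_i1 = 0, n_i2 = 0, outer_used = 0;
  double sg = sg0, se = se0, lam_prev = arma::datum::nan;
  double loglik = arma::datum::nan;
  bool converged = false;

  Pseudo ps = pseudo_uni(u, eta, fam, trials);
  if (!have_vc && !fix_vc) {
    Setup su = make_setup(ps.p, X, P, ps.w);
    double loglam = search_lambda(su, llo, lhi, arma::datum::nan);
    double lambda = std::exp(loglam);
    Prof pr = profile(lambda, su);
    se = pr.sigma_e2;
    sg = lambda * se;
    beta = pr.beta;
    arma::vec rstar = su.ystar - su.Xstar * pr.beta;
    arma::vec t2 = su.s % (rstar + su.U * (pr.a % pr.rr));
    gamma = lambda * (P * (P.t() * t2));
    eta = clamp_eta(X * beta + gamma, clampv, &clamped);
    loglik = pr.loglik;
    lam_prev = lambda;
    n_i2 = 1;
  } else {
    lam_prev = sg / se;
  }

  int outer_max = fix_vc ? 1 : max_outer;
  Prof pr_last;
  bool have_last = false;
  arma::mat cov_fix;
  bool have_cov_fix = false;
  double delta_eta = arma::datum::inf;
  for (int outer = 1; outer <= outer_max; ++outer) {
    outer_used = outer;
    // inner loop 1: relinearize and solve at fixed variance components
    Gls sol;
    bool have_sol = false;
    for (int i1 = 0; i1 < max_i1; ++i1) {
      ps = pseudo_uni(u, eta, fam, trials);
      sol = gls_fixed(ps.p, X, P, ps.w, sg, se);
      have_sol = true;
      beta = sol.beta;
      gamma = sol.gamma;
      arma::vec eta_new = clamp_eta(X * beta + gamma, clampv, &clamped);
      arma::vec den = arma::clamp(arma::abs(eta), 1.0, arma::datum::inf);
      delta_eta = (arma::abs(eta_new - eta) / den).max();
      eta = eta_new;
      ++n_i1;
      if (delta_eta < tol_i1) break;
    }
    if (fix_vc) {
      converged = delta_eta < tol_i1;
      if (have_sol) {
        cov_fix = sol.cov_beta;
        have_cov_fix = true;
      }
      break;
    }
    // inner loop 2: REML on the current pseudo data
    ps = pseudo_uni(u, eta, fam, trials);
    Setup su = make_setup(ps.p, X, P, ps.w);
    double loglam = search_lambda(su, llo, lhi,
                                  std::isfinite(lam_prev) && lam_prev > 0
                                    ? std::log(lam_prev) : arma::datum::nan);
    double lambda = std::exp(loglam);
    Prof pr = profile(lambda, su);
    ++n_i2;
    double sg_new = lambda * pr.sigma_e2, se_new = pr.sigma_e2;
    beta = pr.beta;
    arma::vec rstar = su.ystar - su.Xstar * pr.beta;
    arma::vec t2 = su.s % (rstar + su.U * (pr.a % pr.rr));
    gamma = lambda * (P * (P.t() * t2));
    eta = clamp_eta(X * beta + gamma, clampv, &clamped);
    loglik = pr.loglik;
    lam_prev = lambda;
    pr_last = pr;
    have_last = true;
    double dvc = std::max(std::abs(sg_new - sg), std::abs(se_new - se)) /
      std::max(sg + se, 1e-12);
    sg = sg_new;
    se = se_new;
    if (dvc < tol_outer) {
      converged = true;
      break;
    }
  }

  // covariance of the fixed effects at the reported fit
  arma::mat cov_beta;
  if (fix_vc && have_cov_fix) {
    cov_beta = cov_fix;
  } else if (have_last) {
    cov_beta = se * arma::inv_sympd(pr_last.XtVX);
  } else {
    cov_beta = arma::mat(X.n_cols, X.n_cols, arma::fill::value(arma::datum::nan));
  }
  ps = pseudo_uni(u, eta, fam, trials);
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("se_beta") = arma::sqrt(cov_beta.diag()).eval(),
    Rcpp::Named("cov_beta") = cov_beta,
    Rcpp::Named("gamma") = gamma,
    Rcpp::Named("sigma_g2") = sg,
    Rcpp::Named("sigma_e2") = se,
    Rcpp::Named("p_tilde") = ps.p,
    Rcpp::Named("weights") = ps.w,
    Rcpp::Named("eta") = eta,
    Rcpp::Named("loglik") = loglik,
    Rcpp::Named("inner1") = n_i1,
    Rcpp::Named("inner2") = n_i2,
    Rcpp::Named("outer") = outer_used,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("clamped") = clamped);
}
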