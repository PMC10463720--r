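// Marginal likelihood machinery for the per-gene zero-inflated negative
// binomial mixed model with subject random intercepts in both components.
//
// Model, for gene k (index suppressed), subject i, cell j:
//   Y_ij ~ pi_ij * I{Y_ij = 0} + (1 - pi_ij) * NB(S_ij * lambda_i, d)
//   log(lambda_i)  = alpha + beta * X_i + gamma_i,   gamma_i ~ N(0, sigma^2)
//   logit(pi_ij)   = logit(pi0) + theta * I{Y_ij=0} + eta_i, eta_i ~ N(0, tau^2)
// NB parameterized by mean mu and dispersion d: Var = mu + mu^2/d.
//
// The subject-level random effects (gamma_i, eta_i) are integrated out with
// a joint 2-D Laplace approximation (default) or adaptive Gauss-Hermite
// quadrature on standardized scales u = gamma/sigma, v = eta/tau.
//
// Parameter vector (unconstrained): alpha, beta, log sigma^2, theta,
// log tau^2, log d.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double log1p_exp(double x) {
  // stable log(1 + exp(x))
  if (x > 37.0) return x + std::exp(-x);
  if (x < -37.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double expit(double x) {
  if (x >= 0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

struct CellData {
  const int *y;          // counts
  const double *logS;    // log depth
  const double *lgy1;    // lgamma(y + 1), precomputed (positive cells)
  const int *uyidx;      // index into unique positive y table (-1 for y = 0)
  int n;                 // cells in this subject
  int n_zero;
  int n_pos;
};

struct Params {
  double alpha, beta, sigma, tau, d, ld, lgd, theta, q0;
};

// Evaluate f(u, v) = sum_j loglik_j + standard-normal log-kernels (without
// the -log(2*pi) constant), optionally with gradient and Hessian of the
// data part. lg_tab holds lgamma(uy + d) for the unique positive counts.
static double eval_f(const CellData &cd, const Params &pp, double a_i,
                     double u, double v, const double *lg_tab,
                     bool want_deriv, double *grad, double *hess) {
  const double su = pp.sigma * u, tv = pp.tau * v;
  const double z0 = pp.q0 + pp.theta + tv;  // dropout logit at observed zero
  const double zp = pp.q0 + tv;             // dropout logit at positive count
  const double p0 = expit(z0), q0c = expit(-z0);  // q0c = 1 - p0
  const double pp_ = expit(zp);
  const double lomp = -log1p_exp(zp);        // log(1 - pi) for positive cells

  double ll = 0.0, gu = 0.0, gv = 0.0, huu = 0.0, hvv = 0.0, huv = 0.0;

  for (int j = 0; j < cd.n; ++j) {
    const double lmu = cd.logS[j] + a_i + su;
    const double e = lmu - pp.ld;              // log(mu/d)
    const double w = expit(e);                 // mu/(d+mu)
    const double ldpm = pp.ld + log1p_exp(e);   // log(d + mu)
    if (cd.y[j] == 0) {
      const double log_r = pp.d * (pp.ld - ldpm);  // log NB(0; mu, d)
      const double r = std::exp(log_r);
      const double A = p0 + q0c * r;
      ll += std::log(A);
      if (want_deriv) {
        const double t = pp.d * w;
        const double s = -pp.sigma * t;            // d log r / du
        const double Au = q0c * r * s;
        const double Av = pp.tau * p0 * q0c * (1.0 - r);
        const double iA = 1.0 / A;
        gu += Au * iA;
        gv += Av * iA;
        const double s_u = -pp.sigma * pp.sigma * pp.d * w * (1.0 - w);
        const double Auu = q0c * r * (s * s + s_u);
        const double Avv = pp.tau * pp.tau * p0 * q0c * (1.0 - 2.0 * p0) * (1.0 - r);
        const double Auv = -pp.tau * p0 * q0c * r * s;
        huu += Auu * iA - (Au * iA) * (Au * iA);
        hvv += Avv * iA - (Av * iA) * (Av * iA);
        huv += Auv * iA - (Au * iA) * (Av * iA);
      }
    } else {
      const double y = (double)cd.y[j];
      ll += lomp + lg_tab[cd.uyidx[j]] - pp.lgd - cd.lgy1[j]
            + pp.d * (pp.ld - ldpm) + y * (lmu - ldpm);
      if (want_deriv) {
        gu += pp.sigma * (y * (1.0 - w) - pp.d * w);
        huu += -pp.sigma * pp.sigma * (pp.d + y) * w * (1.0 - w);
      }
    }
  }
  if (want_deriv && cd.n_pos > 0) {
    gv += cd.n_pos * (-pp.tau * pp_);
    hvv += cd.n_pos * (-pp.tau * pp.tau * pp_ * (1.0 - pp_));
  }

  const double f = ll - 0.5 * (u * u + v * v);
  if (want_deriv) {
    grad[0] = gu - u;
    grad[1] = gv - v;
    hess[0] = huu - 1.0;  // f_uu
    hess[1] = huv;        // f_uv
    hess[2] = hvv - 1.0;  // f_vv
  }
  return f;
}

// Damped Newton ascent on f(u, v); returns true on success. On exit (u, v)
// holds the mode, fval = f(mode) and hess the Hessian of f there.
static bool find_mode(const CellData &cd, const Params &pp, double a_i,
                      const double *lg_tab,
                      double &u, double &v, double &fval, double *hess) {
  double grad[2];
  double f = eval_f(cd, pp, a_i, u, v, lg_tab, true, grad, hess);
  if (!std::isfinite(f)) {  // retry from the origin if warm start is bad
    u = 0.0; v = 0.0;
    f = eval_f(cd, pp, a_i, u, v, lg_tab, true, grad, hess);
    if (!std::isfinite(f)) return false;
  }
  // Termination is gradient-based: near the optimum, objective differences
  // sink below double-precision noise long before the (analytic) gradient
  // does, and the Laplace value must be reproducible to ~1e-10 regardless
  // of the warm start.
  const double gtol = 1e-9;
  for (int it = 0; it < 100; ++it) {
    const double gn = std::max(std::fabs(grad[0]), std::fabs(grad[1]));
    if (gn < gtol) break;
    // Newton direction: solve (-H) delta = grad, Levenberg ridge if not PD
    const double m11 = -hess[0], m12 = -hess[1], m22 = -hess[2];
    double lam = 0.0;
    while (m11 + lam <= 1e-10 ||
           (m11 + lam) * (m22 + lam) - m12 * m12 <= 1e-10) {
      lam = (lam == 0.0) ? 1e-4 : lam * 10.0;
      if (lam > 1e8) return false;
    }
    const double det = (m11 + lam) * (m22 + lam) - m12 * m12;
    double d1 = ((m22 + lam) * grad[0] - m12 * grad[1]) / det;
    double d2 = ((m11 + lam) * grad[1] - m12 * grad[0]) / det;
    const double nrm = std::sqrt(d1 * d1 + d2 * d2);
    if (nrm > 10.0) { d1 *= 10.0 / nrm; d2 *= 10.0 / nrm; }

    bool pure = (gn < 1e-3);  // quadratic regime: trust the full step
    if (!pure) {
      // global phase: backtracking line search on f
      double step = 1.0;
      bool moved = false;
      for (int h = 0; h < 30; ++h) {
        const double un = u + step * d1, vn = v + step * d2;
        const double fn =
            eval_f(cd, pp, a_i, un, vn, lg_tab, false, NULL, NULL);
        if (std::isfinite(fn) && fn > f + 1e-13) {
          u = un; v = vn; f = fn;
          moved = true;
          break;
        }
        step *= 0.5;
      }
      if (!moved) {
        pure = true;  // improvements below f-noise: fall through to Newton
      } else {
        f = eval_f(cd, pp, a_i, u, v, lg_tab, true, grad, hess);
        if (!std::isfinite(f)) return false;
        continue;
      }
    }
    // pure Newton step, accepted only if the gradient contracts
    const double ub = u, vb = v, fb = f;
    double gb[2] = {grad[0], grad[1]};
    double hb[3] = {hess[0], hess[1], hess[2]};
    u += d1; v += d2;
    f = eval_f(cd, pp, a_i, u, v, lg_tab, true, grad, hess);
    const double gn2 = std::isfinite(f) ?
        std::max(std::fabs(grad[0]), std::fabs(grad[1])) : R_PosInf;
    if (!(gn2 < gn)) {  // revert and accept the previous point
      u = ub; v = vb; f = fb;
      grad[0] = gb[0]; grad[1] = gb[1];
      hess[0] = hb[0]; hess[1] = hb[1]; hess[2] = hb[2];
      break;
    }
  }
  fval = f;
  return std::isfinite(f);
}

// [[Rcpp::export]]
List cpp_marginal_loglik(NumericVector par, IntegerVector y, NumericVector logS,
                         NumericVector lgy1, IntegerVector uyidx,
                         NumericVector uy, IntegerVector subj_ptr,
                         NumericVector Xsubj, double q0,
                         NumericMatrix modes_in, int method,
                         NumericVector ghx, NumericVector ghw) {
  const int n_subj = Xsubj.size();
  Params pp;
  pp.alpha = par[0];
  pp.beta = par[1];
  pp.sigma = std::exp(0.5 * par[2]);
  pp.theta = par[3];
  pp.tau = std::exp(0.5 * par[4]);
  pp.d = std::exp(par[5]);
  pp.ld = par[5];
  pp.lgd = std::lgamma(pp.d);
  pp.q0 = q0;

  // lgamma(y + d) for the unique positive counts, shared across subjects
  std::vector<double> lg_tab(uy.size());
  for (int k = 0; k < uy.size(); ++k) lg_tab[k] = std::lgamma(uy[k] + pp.d);

  NumericMatrix modes = clone(modes_in);
  double total = 0.0;
  bool ok = true;
  const double LOG2PI = std::log(2.0 * M_PI);

  for (int i = 0; i < n_subj && ok; ++i) {
    CellData cd;
    const int a = subj_ptr[i], b = subj_ptr[i + 1];
    cd.y = &y[0] + a;
    cd.logS = &logS[0] + a;
    cd.lgy1 = &lgy1[0] + a;
    cd.uyidx = &uyidx[0] + a;
    cd.n = b - a;
    cd.n_zero = 0; cd.n_pos = 0;
    for (int j = 0; j < cd.n; ++j) {
      if (cd.y[j] == 0) cd.n_zero++; else cd.n_pos++;
    }
    const double a_i = pp.alpha + pp.beta * Xsubj[i];

    double u = modes(i, 0), v = modes(i, 1), fmode, hess[3];
    if (!find_mode(cd, pp, a_i, lg_tab.data(), u, v, fmode, hess)) { ok = false; break; }
    modes(i, 0) = u; modes(i, 1) = v;

    const double m11 = -hess[0], m12 = -hess[1], m22 = -hess[2];
    const double detM = m11 * m22 - m12 * m12;
    if (!(detM > 0.0) || !(m11 > 0.0)) { ok = false; break; }

    if (method == 0) {  // Laplace
      total += fmode - 0.5 * std::log(detM);
    } else {            // adaptive Gauss-Hermite (ghx/ghw physicists' rule)
      // Sigma = M^{-1}, lower Cholesky C
      const double s11 = m22 / detM, s12 = -m12 / detM, s22 = m11 / detM;
      const double c11 = std::sqrt(s11);
      const double c21 = s12 / c11;
      const double c22 = std::sqrt(s22 - c21 * c21);
      const int K = ghx.size();
      double lse = R_NegInf;
      for (int ii = 0; ii < K; ++ii) {
        for (int jj = 0; jj < K; ++jj) {
          const double t1 = ghx[ii], t2 = ghx[jj];
          const double uu = u + M_SQRT2 * c11 * t1;
          const double vv = v + M_SQRT2 * (c21 * t1 + c22 * t2);
          const double fv = eval_f(cd, pp, a_i, uu, vv, lg_tab.data(), false, NULL, NULL);
          const double term = std::log(ghw[ii]) + std::log(ghw[jj]) + fv +
                              t1 * t1 + t2 * t2;
          if (std::isfinite(term)) {
            if (term > lse)
              lse = term + log1p_exp(lse - term);
            else
              lse = lse + log1p_exp(term - lse);
          }
        }
      }
      total += lse + std::log(2.0) + std::log(c11) + std::log(c22) - LOG2PI;
    }
  }

  return List::create(_["ll"] = ok ? total : R_NegInf,
                      _["modes"] = modes,
                      _["ok"] = ok);
}
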