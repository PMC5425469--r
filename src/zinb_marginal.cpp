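#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Zero-inflated negative binomial log-pmf (NB2: Var = mu + mu^2/theta).
// log_mu passed directly so the random intercept can be added on the log scale.
static inline double zinb_logpmf(double y, double log_mu, double theta,
                                 double log_pi, double log1m_pi) {
  double mu = std::exp(log_mu);
  // log P_NB(0) = theta * (log theta - log(theta + mu))
  double lp0 = theta * (std::log(theta) - std::log(theta + mu));
  if (y == 0.0) {
    // log(pi + (1 - pi) * exp(lp0)) via log-sum-exp; log_pi may be -Inf.
    double a = log_pi;
    double b = log1m_pi + lp0;
    if (a == R_NegInf) return b;
    double m = std::max(a, b);
    return m + std::log(std::exp(a - m) + std::exp(b - m));
  }
  double ll = std::lgamma(y + theta) - std::lgamma(theta) - std::lgamma(y + 1.0)
    + lp0 + y * (log_mu - std::log(theta + mu));
  return log1m_pi + ll;
}

// Everything a group-integrand evaluation needs that does not depend on u.
// lgc caches lgamma(y+theta) - lgamma(theta) - lgamma(y+1) per row (zero
// for y == 0 rows), so the repeated evaluations during mode search and
// quadrature cost no lgamma calls.
struct CallCtx {
  const arma::vec& y;
  const arma::vec& eta;
  const arma::vec& lgc;
  double theta, ltheta, log_pi, log1m_pi, sigma;
};

static double group_logint(const CallCtx& c, const arma::uvec& idx,
                           double u) {
  double s = 0.0;
  for (arma::uword k = 0; k < idx.n_elem; ++k) {
    arma::uword i = idx[k];
    double log_mu = c.eta[i] + u;
    double mu = std::exp(log_mu);
    double lden = std::log(c.theta + mu);
    double lp0 = c.theta * (c.ltheta - lden);
    if (c.y[i] == 0.0) {
      double b = c.log1m_pi + lp0;
      if (c.log_pi == R_NegInf) { s += b; continue; }
      double m = std::max(c.log_pi, b);
      s += m + std::log(std::exp(c.log_pi - m) + std::exp(b - m));
    } else {
      s += c.log1m_pi + c.lgc[i] + lp0 + c.y[i] * (log_mu - lden);
    }
  }
  s += R::dnorm(u, 0.0, c.sigma, 1);
  return s;
}

// Locate the mode of the group integrand by damped Newton with central
// finite differences; returns the mode and -f'' there through references.
static void group_mode(const CallCtx& c, const arma::uvec& idx,
                       double u_start, double& u_mode, double& neg_h2) {
  double u = u_start;
  const double h = 1e-4;
  double f0 = group_logint(c, idx, u);
  for (int it = 0; it < 60; ++it) {
    double fp = group_logint(c, idx, u + h);
    double fm = group_logint(c, idx, u - h);
    double g1 = (fp - fm) / (2.0 * h);
    double g2 = (fp - 2.0 * f0 + fm) / (h * h);
    if (!std::isfinite(g1) || !std::isfinite(g2)) break;
    double step;
    if (g2 < -1e-12) {
      step = -g1 / g2;                 // Newton on a locally concave integrand
    } else {
      step = (g1 > 0 ? 1.0 : -1.0) *
        std::min(0.5, std::fabs(g1) * c.sigma * c.sigma);
    }
    if (std::fabs(step) > 5.0) step = (step > 0 ? 5.0 : -5.0);
    // backtrack until the objective does not decrease
    double f1 = group_logint(c, idx, u + step);
    int bt = 0;
    while (f1 < f0 && bt < 30) { step *= 0.5; ++bt;
      f1 = group_logint(c, idx, u + step);
    }
    u += step; f0 = f1;
    if (std::fabs(step) < 1e-8) break;
  }
  double fp = group_logint(c, idx, u + h);
  double fm = group_logint(c, idx, u - h);
  neg_h2 = -((fp - 2.0 * f0 + fm) / (h * h));
  if (!(neg_h2 > 0.0)) neg_h2 = 1.0 / (c.sigma * c.sigma);  // safeguard
  u_mode = u;
}

// [[Rcpp::export(name = ".zinb_marginal_cpp")]]
List zinb_marginal_cpp(const arma::vec& beta, double theta, double pi,
                       double sigma, const arma::vec& y, const arma::mat& X,
                       const arma::vec& offset, const arma::ivec& group,
                       int n_groups, const arma::vec& ghx, const arma::vec& ghw,
                       const arma::vec& u_start) {
  arma::vec eta = X * beta + offset;
  double log_pi = (pi > 0.0) ? std::log(pi) : R_NegInf;
  double log1m_pi = std::log1p(-pi);
  const int nq = ghx.n_elem;
  double ll = 0.0;
  arma::vec u_hat(n_groups, arma::fill::zeros);

  // per-call lgamma constants (independent of the random intercept)
  double lg_theta = std::lgamma(theta);
  arma::vec lgc(y.n_elem, arma::fill::zeros);
  for (arma::uword i = 0; i < y.n_elem; ++i)
    if (y[i] > 0.0)
      lgc[i] = std::lgamma(y[i] + theta) - lg_theta - std::lgamma(y[i] + 1.0);
  CallCtx ctx{y, eta, lgc, theta, std::log(theta), log_pi, log1m_pi, sigma};

  // group row indices
  std::vector<std::vector<arma::uword>> rows(n_groups);
  for (arma::uword i = 0; i < y.n_elem; ++i) rows[group[i]].push_back(i);

  for (int g = 0; g < n_groups; ++g) {
    arma::uvec idx = arma::conv_to<arma::uvec>::from(rows[g]);
    if (idx.n_elem == 0) continue;
    if (sigma < 1e-8) {
      // degenerate random effect: evaluate at u = 0, no Gaussian factor
      CallCtx c0 = ctx; c0.sigma = 1.0;  // sigma unused on this path
      ll += group_logint(c0, idx, 0.0) - R::dnorm(0.0, 0.0, 1.0, 1);
      continue;
    }
    double u0, neg_h2;
    group_mode(ctx, idx, u_start[g], u0, neg_h2);
    u_hat[g] = u0;
    double s = 1.0 / std::sqrt(neg_h2);
    if (nq == 1) {
      // Laplace approximation
      double f0 = group_logint(ctx, idx, u0);
      ll += f0 + 0.5 * std::log(2.0 * M_PI) + std::log(s);
    } else {
      // adaptive Gauss-Hermite centred at the mode, scaled by the curvature
      double m = R_NegInf;
      arma::vec terms(nq);
      for (int q = 0; q < nq; ++q) {
        double u = u0 + M_SQRT2 * s * ghx[q];
        terms[q] = std::log(ghw[q]) + ghx[q] * ghx[q] +
          group_logint(ctx, idx, u);
        if (terms[q] > m) m = terms[q];
      }
      double acc = 0.0;
      for (int q = 0; q < nq; ++q) acc += std::exp(terms[q] - m);
      ll += std::log(M_SQRT2 * s) + m + std::log(acc);
    }
  }
  return List::create(_["loglik"] = ll, _["u_hat"] = u_hat);
}

// Vectorised ZINB log-pmf used by the R-level density function.
// [[Rcpp::export(name = ".zinb_logpmf_cpp")]]
NumericVector zinb_logpmf_cpp(const arma::vec& y, const arma::vec& mu,
                              double theta, double pi) {
  double log_pi = (pi > 0.0) ? std::log(pi) : R_NegInf;
  double log1m_pi = std::log1p(-pi);
  NumericVector out(y.n_elem);
  for (arma::uword i = 0; i < y.n_elem; ++i)
    out[i] = zinb_logpmf(y[i], std::log(mu[i]), theta, log_pi, log1m_pi);
  return out;
}
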