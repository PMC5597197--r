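#include <Rcpp.h>
using namespace Rcpp;

// Linear predictor eta_i = theta[0] + offset_i + sum_j X(i,j) * theta[1+j].
static inline void fill_eta(const NumericVector& theta, const NumericMatrix& X,
                            const NumericVector& offset, std::vector<double>& eta) {
  const int n = X.nrow(), d = X.ncol();
  if (n == 0) return;
  for (int i = 0; i < n; ++i) eta[i] = theta[0] + offset[i];
  for (int j = 0; j < d; ++j) {
    const double b = theta[1 + j];
    if (b == 0.0) continue;
    const double* col = &X(0, j);
    for (int i = 0; i < n; ++i) eta[i] += b * col[i];
  }
}

// Negative binomial log-pmf parameterized by mean mu and size r, written as
// sum_{k<y} log(r+k) - lgamma(y+1) + r log r - (r+y) log(r+mu) + y log mu
// for small y (cheaper than two lgamma calls), with the lgamma form as
// fallback. lg_y1 = lgamma(y+1) precomputed by the caller.
static inline double nb_logpmf(int y, double mu, double r, double lg_y1) {
  double acc;
  if (y <= 30) {
    acc = 0.0;
    for (int k = 0; k < y; ++k) acc += std::log(r + k);
  } else {
    acc = R::lgammafn(y + r) - R::lgammafn(r);
  }
  return acc - lg_y1 + r * std::log(r) - (r + y) * std::log(r + mu) +
         (y > 0 ? y * std::log(mu) : 0.0);
}

// Count-family log-likelihood over a given linear predictor: Poisson at
// omega == 1, negative binomial (variance omega * mu) for omega > 1, and an
// equal-mean two-point binomial mixture for omega < 1 (exact mean and index
// of dispersion where feasible; -Inf where the dispersion is unattainable,
// so such proposals are rejected).
static double count_ll_eta(const std::vector<double>& eta, const IntegerVector& y,
                           const std::vector<double>& lg_y1, double omega) {
  const int n = (int) eta.size();
  double ll = 0.0;
  if (std::fabs(omega - 1.0) < 1e-12) {
    for (int i = 0; i < n; ++i) {
      const double mu = std::exp(eta[i]);
      if (!R_finite(mu)) return R_NegInf;
      ll += (y[i] > 0 ? y[i] * eta[i] : 0.0) - mu - lg_y1[i];
    }
  } else if (omega > 1.0) {
    const double inv_ex = 1.0 / (omega - 1.0);
    for (int i = 0; i < n; ++i) {
      const double mu = std::exp(eta[i]);
      if (!R_finite(mu) || mu <= 0.0) return R_NegInf;
      ll += nb_logpmf(y[i], mu, mu * inv_ex, lg_y1[i]);
    }
  } else {
    const double pbar = 1.0 - omega;
    for (int i = 0; i < n; ++i) {
      const double mu = std::exp(eta[i]);
      if (!R_finite(mu) || mu <= 0.0) return R_NegInf;
      const double n0 = std::floor(mu / pbar);
      if (n0 < 1.0 || n0 < mu) return R_NegInf;  // dispersion not attainable
      const double p0 = mu / n0, p1 = mu / (n0 + 1.0);
      double w = (pbar - p1) / (p0 - p1);
      if (w < 0.0) w = 0.0; else if (w > 1.0) w = 1.0;
      const double pr = w * R::dbinom(y[i], n0, p0, 0) +
                        (1.0 - w) * R::dbinom(y[i], n0 + 1.0, p1, 0);
      if (pr <= 0.0) return R_NegInf;
      ll += std::log(pr);
    }
  }
  return R_finite(ll) ? ll : R_NegInf;
}

// Zero-inflated cumulative beta log-likelihood for Braun-Blanquet classes
// 0-5 with cut points 0.05/0.25/0.50/0.75; eta is the logit of the global
// latent mean (1 - pi0) * mu_beta.
static double abund_ll_eta(const std::vector<double>& eta, const IntegerVector& y,
                           double phi, double pi0) {
  static const double cuts[4] = {0.05, 0.25, 0.50, 0.75};
  if (!R_finite(phi) || phi <= 0.0) return R_NegInf;
  const int n = (int) eta.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double pr;
    if (y[i] == 0) {
      pr = pi0;
    } else {
      const double m = 1.0 / (1.0 + std::exp(-eta[i]));
      const double ratio = m / (1.0 - pi0);
      if (ratio >= 1.0) return R_NegInf;  // infeasible global mean
      double mu_b = ratio;
      if (mu_b < 1e-6) mu_b = 1e-6; else if (mu_b > 1.0 - 1e-6) mu_b = 1.0 - 1e-6;
      const double a = mu_b * phi, b = (1.0 - mu_b) * phi;
      const int k = y[i];
      const double lo = (k == 1) ? 0.0 : R::pbeta(cuts[k - 2], a, b, 1, 0);
      const double hi = (k == 5) ? 1.0 : R::pbeta(cuts[k - 1], a, b, 1, 0);
      pr = (1.0 - pi0) * (hi - lo);
    }
    if (pr <= 0.0) return R_NegInf;
    ll += std::log(pr);
  }
  return R_finite(ll) ? ll : R_NegInf;
}

static std::vector<double> lgamma_y1(const IntegerVector& y) {
  std::vector<double> out(y.size());
  for (int i = 0; i < (int) y.size(); ++i) out[i] = R::lgammafn(y[i] + 1.0);
  return out;
}

// [[Rcpp::export]]
double ll_richness_cpp(NumericVector theta, NumericMatrix X, IntegerVector y,
                       NumericVector offset) {
  const int d = X.ncol();
  if (theta.size() != d + 2) stop("theta must have length ncol(X) + 2");
  const double omega = std::exp(theta[d + 1]);
  if (!R_finite(omega) || omega <= 0.0) return R_NegInf;
  std::vector<double> eta(X.nrow());
  fill_eta(theta, X, offset, eta);
  return count_ll_eta(eta, y, lgamma_y1(y), omega);
}

// [[Rcpp::export]]
double ll_abundance_cpp(NumericVector theta, NumericMatrix X, IntegerVector y,
                        NumericVector offset) {
  const int d = X.ncol();
  if (theta.size() != d + 3) stop("theta must have length ncol(X) + 3");
  const double phi = std::exp(theta[d + 1]);
  const double pi0 = 1.0 / (1.0 + std::exp(-theta[d + 2]));
  std::vector<double> eta(X.nrow());
  fill_eta(theta, X, offset, eta);
  return abund_ll_eta(eta, y, phi, pi0);
}

// ---- fast Metropolis-within-Gibbs sweep -------------------------------
//
// One component-wise sweep over the full parameter vector with the model
// likelihood evaluated in place (the linear predictor updated
// incrementally per coordinate). Proposals use R's RNG (norm_rand /
// unif_rand), so runs remain a pure function of the R seed.
//
// kind: 0 = richness (one nuisance, log omega), 1 = abundance (log phi,
// logit pi0). theta: xi0, one coefficient per design column, nuisance.
// A (optional, 0x0 = identity): linear map from the sampled coefficient
// block gamma to the model coefficients xi = A gamma on which the
// independent N(0, prior_sd) priors apply (used when the design has been
// orthogonalized for sampling).
// [[Rcpp::export]]
List mwg_sweep_cpp(NumericVector theta, NumericVector scales, double temperature,
                   int kind, NumericMatrix X, IntegerVector y,
                   NumericVector offset, double prior_sd,
                   LogicalVector has_prior, NumericMatrix A) {
  const int n = X.nrow(), d = X.ncol();
  const int p = theta.size();
  const int n_coef = d + 1;
  const bool use_A = A.nrow() == n_coef && A.ncol() == n_coef;
  NumericVector th = clone(theta);
  std::vector<double> eta(n), eta_prop(n);
  std::vector<double> lg = lgamma_y1(y);
  fill_eta(th, X, offset, eta);
  double omega = 0.0, phi = 0.0, pi0 = 0.0;
  if (kind == 0) omega = std::exp(th[p - 1]);
  else { phi = std::exp(th[p - 2]); pi0 = 1.0 / (1.0 + std::exp(-th[p - 1])); }
  double cur_ll = (kind == 0) ? count_ll_eta(eta, y, lg, omega)
                              : abund_ll_eta(eta, y, phi, pi0);

  // prior over the coefficient block (through A when orthogonalized)
  std::vector<double> xi(n_coef);
  auto coef_prior = [&](const NumericVector& t) {
    double s = 0.0;
    if (use_A) {
      for (int r = 0; r < n_coef; ++r) {
        double acc = 0.0;
        for (int c = 0; c < n_coef; ++c) acc += A(r, c) * t[c];
        xi[r] = acc;
      }
      for (int r = 0; r < n_coef; ++r)
        if (has_prior[r]) s += R::dnorm4(xi[r], 0.0, prior_sd, 1);
    } else {
      for (int r = 0; r < n_coef; ++r)
        if (has_prior[r]) s += R::dnorm4(t[r], 0.0, prior_sd, 1);
    }
    return s;
  };
  double cur_cprior = coef_prior(th);
  double cur_nprior = 0.0;
  for (int j = n_coef; j < p; ++j)
    if (has_prior[j]) cur_nprior += R::dnorm4(th[j], 0.0, prior_sd, 1);

  IntegerVector accepted(p);
  for (int j = 0; j < p; ++j) {
    const double old = th[j];
    const double prop = old + norm_rand() * scales[j];
    double ll_new, prior_new_c = cur_cprior, prior_new_n = cur_nprior;
    const bool is_eta_coord = j < n_coef;
    if (is_eta_coord) {
      const double delta = prop - old;
      if (j == 0) {
        for (int i = 0; i < n; ++i) eta_prop[i] = eta[i] + delta;
      } else {
        const double* col = &X(0, j - 1);
        for (int i = 0; i < n; ++i) eta_prop[i] = eta[i] + delta * col[i];
      }
      ll_new = (kind == 0) ? count_ll_eta(eta_prop, y, lg, omega)
                           : abund_ll_eta(eta_prop, y, phi, pi0);
      th[j] = prop;
      prior_new_c = coef_prior(th);
      th[j] = old;
    } else {
      if (kind == 0) {
        ll_new = count_ll_eta(eta, y, lg, std::exp(prop));
      } else if (j == p - 2) {
        ll_new = abund_ll_eta(eta, y, std::exp(prop), pi0);
      } else {
        ll_new = abund_ll_eta(eta, y, phi, 1.0 / (1.0 + std::exp(-prop)));
      }
      if (has_prior[j])
        prior_new_n += R::dnorm4(prop, 0.0, prior_sd, 1) -
                       R::dnorm4(old, 0.0, prior_sd, 1);
    }
    const double lp_new = ll_new + prior_new_c + prior_new_n;
    const double lp_cur = cur_ll + cur_cprior + cur_nprior;
    if (R_finite(ll_new) &&
        std::log(unif_rand()) < (lp_new - lp_cur) / temperature) {
      th[j] = prop;
      cur_ll = ll_new;
      cur_cprior = prior_new_c;
      cur_nprior = prior_new_n;
      accepted[j] = 1;
      if (is_eta_coord) eta.swap(eta_prop);
      else if (kind == 0) omega = std::exp(prop);
      else if (j == p - 2) phi = std::exp(prop);
      else pi0 = 1.0 / (1.0 + std::exp(-prop));
    }
  }
  return List::create(_["theta"] = th, _["lp"] = cur_ll + cur_cprior + cur_nprior,
                      _["accepted"] = accepted);
}
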