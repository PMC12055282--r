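#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Bernoulli log-density on the logit scale:
//   y = 1 -> -log(1 + e^-eta),  y = 0 -> -log(1 + e^eta)
static inline double bern_ll(int y, double eta) {
  return (y == 1) ? -log1pexp_(-eta) : -log1pexp_(eta);
}

// Marginal log-likelihood of a random-intercept logistic model by adaptive
// Gauss-Hermite quadrature.
//
// eta0   : fixed part of the linear predictor (X beta + offset), grouped so
//          that records of individual g occupy positions gstart[g]..gstart[g+1]-1
//          (0-based, gstart has G+1 entries)
// y      : binary responses, same ordering
// sigma  : random-intercept SD (>= 0); sigma == 0 returns the degenerate
//          conditional log-likelihood at u = 0
// z, w   : Gauss-Hermite nodes and weights for weight function exp(-z^2)
//
// Per individual the integrand exp(h(u)), h(u) = sum_j log p(y_j | u) -
// u^2/(2 sigma^2), is centred at its mode (Newton) and scaled by the
// curvature there, the standard adaptive rule for binary mixed models.
// [[Rcpp::export(name = ".agq_loglik_cpp")]]
double agq_loglik_cpp(NumericVector eta0, IntegerVector y, IntegerVector gstart,
                      double sigma, NumericVector z, NumericVector w) {
  const int G = gstart.size() - 1;
  const int K = z.size();
  double total = 0.0;

  if (sigma <= 0.0) {
    const int n = eta0.size();
    for (int i = 0; i < n; ++i) total += bern_ll(y[i], eta0[i]);
    return total;
  }

  const double inv_s2 = 1.0 / (sigma * sigma);
  const double log_norm = -std::log(sigma) - 0.5 * std::log(2.0 * M_PI);

  for (int g = 0; g < G; ++g) {
    const int a = gstart[g], b = gstart[g + 1];

    // Newton iterations for the conditional mode of h(u)
    double u = 0.0;
    double h = 0.0, hpp = 0.0;
    for (int it = 0; it < 100; ++it) {
      double hp = -u * inv_s2;
      hpp = -inv_s2;
      for (int j = a; j < b; ++j) {
        double e = eta0[j] + u;
        double p = 1.0 / (1.0 + std::exp(-e));
        hp += y[j] - p;
        hpp -= p * (1.0 - p);
      }
      double step = -hp / hpp;
      // h is strictly concave in u, so undamped Newton converges; cap the
      // step to stay safe with extreme linear predictors
      if (step > 10.0) step = 10.0;
      if (step < -10.0) step = -10.0;
      u += step;
      if (std::fabs(step) < 1e-12) break;
    }

    // h and curvature at the mode
    h = -0.5 * u * u * inv_s2;
    hpp = -inv_s2;
    for (int j = a; j < b; ++j) {
      double e = eta0[j] + u;
      h += bern_ll(y[j], e);
      double p = 1.0 / (1.0 + std::exp(-e));
      hpp -= p * (1.0 - p);
    }
    const double s = 1.0 / std::sqrt(-hpp);

    // sum_k w_k exp(h(u + sqrt2 s z_k) + z_k^2 - h(mode))
    double acc = 0.0;
    const double sqrt2s = M_SQRT2 * s;
    for (int k = 0; k < K; ++k) {
      double uk = u + sqrt2s * z[k];
      double hk = -0.5 * uk * uk * inv_s2;
      for (int j = a; j < b; ++j) hk += bern_ll(y[j], eta0[j] + uk);
      acc += w[k] * std::exp(hk + z[k] * z[k] - h);
    }

    total += h + std::log(sqrt2s * acc) + log_norm;
  }
  return total;
}

// Conditional (given u) log-likelihood: sum of Bernoulli log-densities at
// eta = eta0 + u[individual].
// [[Rcpp::export(name = ".cond_loglik_cpp")]]
double cond_loglik_cpp(NumericVector eta0, IntegerVector y, IntegerVector gidx,
                       NumericVector u) {
  const int n = eta0.size();
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += bern_ll(y[i], eta0[i] + u[gidx[i]]);
  return total;
}

// Marginal log-likelihood and its gradient with respect to (beta, log sigma).
//
// The gradient is the posterior-expected score, E_post[d log f/d theta],
// evaluated with the same adaptive quadrature rule as the likelihood:
//   d/d beta_r  : sum_k wt_k sum_j (y_j - p_j(u_k)) X(j, r)
//   d/d log sig : sum_k wt_k (u_k^2 / sigma^2 - 1)
// with wt_k the normalized quadrature weights of the posterior of u.
// With sigma_zero = true the degenerate conditional likelihood at u = 0 is
// returned (gradient over beta only, log-sigma slot set to 0).
// [[Rcpp::export(name = ".agq_loglik_grad_cpp")]]
List agq_loglik_grad_cpp(NumericMatrix X, NumericVector off, NumericVector beta,
                         double logsigma, IntegerVector y, IntegerVector gstart,
                         NumericVector z, NumericVector w, bool sigma_zero) {
  const int n = X.nrow(), p = X.ncol();
  const int G = gstart.size() - 1;
  const int K = z.size();
  NumericVector grad(p + 1);
  double total = 0.0;

  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double e = off[i];
    for (int r = 0; r < p; ++r) e += X(i, r) * beta[r];
    eta0[i] = e;
  }

  if (sigma_zero) {
    for (int i = 0; i < n; ++i) {
      total += bern_ll(y[i], eta0[i]);
      double pr = 1.0 / (1.0 + std::exp(-eta0[i]));
      for (int r = 0; r < p; ++r) grad[r] += (y[i] - pr) * X(i, r);
    }
    return List::create(_["value"] = total, _["gradient"] = grad);
  }

  const double sigma = std::exp(logsigma);
  const double inv_s2 = 1.0 / (sigma * sigma);
  const double log_norm = -std::log(sigma) - 0.5 * std::log(2.0 * M_PI);
  std::vector<double> wt(K), gb(p);

  for (int g = 0; g < G; ++g) {
    const int a = gstart[g], b = gstart[g + 1];
    double u = 0.0, hpp = 0.0;
    for (int it = 0; it < 100; ++it) {
      double hp = -u * inv_s2;
      hpp = -inv_s2;
      for (int j = a; j < b; ++j) {
        double e = eta0[j] + u;
        double pr = 1.0 / (1.0 + std::exp(-e));
        hp += y[j] - pr;
        hpp -= pr * (1.0 - pr);
      }
      double step = -hp / hpp;
      if (step > 10.0) step = 10.0;
      if (step < -10.0) step = -10.0;
      u += step;
      if (std::fabs(step) < 1e-12) break;
    }
    double h0 = -0.5 * u * u * inv_s2;
    hpp = -inv_s2;
    for (int j = a; j < b; ++j) {
      double e = eta0[j] + u;
      h0 += bern_ll(y[j], e);
      double pr = 1.0 / (1.0 + std::exp(-e));
      hpp -= pr * (1.0 - pr);
    }
    const double s = 1.0 / std::sqrt(-hpp);
    const double sqrt2s = M_SQRT2 * s;

    double S = 0.0, gs = 0.0;
    std::fill(gb.begin(), gb.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      double uk = u + sqrt2s * z[k];
      double hk = -0.5 * uk * uk * inv_s2;
      for (int j = a; j < b; ++j) hk += bern_ll(y[j], eta0[j] + uk);
      double wk = w[k] * std::exp(hk + z[k] * z[k] - h0);
      S += wk;
      for (int j = a; j < b; ++j) {
        double pr = 1.0 / (1.0 + std::exp(-(eta0[j] + uk)));
        double resid = (y[j] - pr) * wk;
        for (int r = 0; r < p; ++r) gb[r] += resid * X(j, r);
      }
      gs += wk * (uk * uk * inv_s2 - 1.0);
    }
    total += h0 + std::log(sqrt2s * S) + log_norm;
    for (int r = 0; r < p; ++r) grad[r] += gb[r] / S;
    grad[p] += gs / S;
  }
  return List::create(_["value"] = total, _["gradient"] = grad);
}
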