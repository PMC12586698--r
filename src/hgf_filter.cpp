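#include <Rcpp.h>
using namespace Rcpp;

// Node layout: k = i + 4*j (0-based), i = from-category, j = to-category,
// matching the column-major [trial, from, to] arrays on the R side.

static inline double logistic(double x) {
  return x >= 0 ? 1.0 / (1.0 + std::exp(-x)) : std::exp(x) / (1.0 + std::exp(x));
}

static const double EXP_CAP = 1e12;    // clamp on exp(omega)
static const double PI_FLOOR = 1e-12;  // precision floor

// Full filter pass: trajectory arrays plus trial-wise belief regressors.
// [[Rcpp::export]]
List hgf_filter_cpp(IntegerVector stimuli, LogicalVector new_session,
                    double omega, double mu0, double pi0) {
  const int n = stimuli.size();
  const double vol = std::min(std::exp(omega), EXP_CAP);

  std::vector<double> mu(16, mu0), pi(16, pi0);
  NumericVector out_mu(n * 16), out_pi(n * 16), out_mu_hat(n * 16),
      out_pi_hat(n * 16), out_delta(n * 16, NA_REAL), out_pred(n * 16);
  NumericVector surprise(n), ue(n), uu(n);
  IntegerVector from(n, NA_INTEGER), to(n, NA_INTEGER);

  double mu_hat[16], pi_hat[16], sl[16], pred[16];

  for (int t = 0; t < n; ++t) {
    // prediction step on all 16 nodes: time passes for every transition
    for (int k = 0; k < 16; ++k) {
      mu_hat[k] = mu[k];
      pi_hat[k] = std::max(1.0 / (1.0 / pi[k] + vol), PI_FLOOR);
      sl[k] = logistic(mu_hat[k]);
    }
    for (int i = 0; i < 4; ++i) {
      double rs = 0.0;
      for (int j = 0; j < 4; ++j) rs += sl[i + 4 * j];
      for (int j = 0; j < 4; ++j) pred[i + 4 * j] = sl[i + 4 * j] / rs;
    }

    if (new_session[t]) {
      // no incoming transition: uniform fallback surprise, no update
      surprise[t] = std::log(4.0);
      ue[t] = 0.0;
      uu[t] = 0.0;
      for (int k = 0; k < 16; ++k) { mu[k] = mu_hat[k]; pi[k] = pi_hat[k]; }
    } else {
      const int i = stimuli[t - 1] - 1, j = stimuli[t] - 1;
      const int kk = i + 4 * j;
      from[t] = i + 1;
      to[t] = j + 1;
      surprise[t] = -std::log(pred[kk]);
      ue[t] = sl[kk] * (1.0 - sl[kk]) / pi_hat[kk];
      uu[t] = ue[t] * vol;
      // binary-child update of the active row; 1 for the observed
      // transition, 0 for its three siblings
      for (int jj = 0; jj < 4; ++jj) {
        const int k = i + 4 * jj;
        const double b = sl[k];
        const double delta = (jj == j ? 1.0 : 0.0) - b;
        const double pin = pi_hat[k] + b * (1.0 - b);
        mu[k] = mu_hat[k] + delta / pin;
        pi[k] = pin;
        out_delta[t + n * k] = delta;
      }
      // inactive rows adopt their prediction as the posterior
      for (int ii = 0; ii < 4; ++ii) {
        if (ii == i) continue;
        for (int jj = 0; jj < 4; ++jj) {
          const int k = ii + 4 * jj;
          mu[k] = mu_hat[k];
          pi[k] = pi_hat[k];
        }
      }
    }

    for (int k = 0; k < 16; ++k) {
      out_mu[t + n * k] = mu[k];
      out_pi[t + n * k] = pi[k];
      out_mu_hat[t + n * k] = mu_hat[k];
      out_pi_hat[t + n * k] = pi_hat[k];
      out_pred[t + n * k] = pred[k];
    }
  }

  return List::create(
      _["mu"] = out_mu, _["pi"] = out_pi, _["mu_hat"] = out_mu_hat,
      _["pi_hat"] = out_pi_hat, _["delta"] = out_delta,
      _["prediction"] = out_pred, _["from"] = from, _["to"] = to,
      _["surprise"] = surprise, _["u_expected"] = ue, _["u_unexpected"] = uu);
}

// Fast path for inference: only the three belief regressors, no trajectory
// storage.  Must stay numerically identical to hgf_filter_cpp.
// [[Rcpp::export]]
NumericMatrix hgf_regressors_cpp(IntegerVector stimuli, LogicalVector new_session,
                                 double omega, double mu0, double pi0) {
  const int n = stimuli.size();
  const double vol = std::min(std::exp(omega), EXP_CAP);

  std::vector<double> mu(16, mu0), pi(16, pi0);
  NumericMatrix out(n, 3);
  double mu_hat[16], pi_hat[16], sl[16];

  for (int t = 0; t < n; ++t) {
    for (int k = 0; k < 16; ++k) {
      mu_hat[k] = mu[k];
      pi_hat[k] = std::max(1.0 / (1.0 / pi[k] + vol), PI_FLOOR);
      sl[k] = logistic(mu_hat[k]);
    }
    if (new_session[t]) {
      out(t, 0) = std::log(4.0);
      out(t, 1) = 0.0;
      out(t, 2) = 0.0;
      for (int k = 0; k < 16; ++k) { mu[k] = mu_hat[k]; pi[k] = pi_hat[k]; }
    } else {
      const int i = stimuli[t - 1] - 1, j = stimuli[t] - 1;
      const int kk = i + 4 * j;
      double rs = 0.0;
      for (int jj = 0; jj < 4; ++jj) rs += sl[i + 4 * jj];
      out(t, 0) = -std::log(sl[kk] / rs);
      out(t, 1) = sl[kk] * (1.0 - sl[kk]) / pi_hat[kk];
      out(t, 2) = out(t, 1) * vol;
      for (int jj = 0; jj < 4; ++jj) {
        const int k = i + 4 * jj;
        const double b = sl[k];
        const double delta = (jj == j ? 1.0 : 0.0) - b;
        const double pin = pi_hat[k] + b * (1.0 - b);
        mu[k] = mu_hat[k] + delta / pin;
        pi[k] = pin;
      }
      for (int ii = 0; ii < 4; ++ii) {
        if (ii == i) continue;
        for (int jj = 0; jj < 4; ++jj) {
          const int k = ii + 4 * jj;
          mu[k] = mu_hat[k];
          pi[k] = pi_hat[k];
        }
      }
    }
  }
  return out;
}
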