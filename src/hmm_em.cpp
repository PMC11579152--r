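#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static inline double dnorm_val(double x, double mu, double var) {
  return std::exp(-0.5 * (x - mu) * (x - mu) / var) / std::sqrt(2.0 * M_PI * var);
}

// Baum-Welch EM for a univariate Gaussian HMM with free initial distribution.
// Scaled forward/backward recursions; emission variances floored at var_floor.
// [[Rcpp::export]]
List hmm_em_cpp(NumericVector x, NumericVector init0, NumericMatrix trans0,
                NumericVector means0, NumericVector vars0,
                int max_iter, double tol, double var_floor) {
  const int T = x.size(), M = means0.size();
  NumericVector init = clone(init0), means = clone(means0), vars = clone(vars0);
  NumericMatrix trans = clone(trans0);
  NumericMatrix alpha(T, M), beta(T, M), B(T, M), gamma(T, M);
  NumericVector scale(T);
  double ll = R_NegInf, ll_prev = R_NegInf;
  int n_iter = 0;
  bool converged = false, floored = false, decreased = false;

  for (;;) {
    for (int t = 0; t < T; ++t)
      for (int m = 0; m < M; ++m) B(t, m) = dnorm_val(x[t], means[m], vars[m]);

    // forward
    double s = 0;
    for (int m = 0; m < M; ++m) { alpha(0, m) = init[m] * B(0, m); s += alpha(0, m); }
    if (s <= 0 || !R_FINITE(s)) { // total underflow: fall back to uniform
      for (int m = 0; m < M; ++m) alpha(0, m) = 1.0 / M;
      s = DBL_MIN;
    } else {
      for (int m = 0; m < M; ++m) alpha(0, m) /= s;
    }
    scale[0] = s;
    for (int t = 1; t < T; ++t) {
      s = 0;
      for (int j = 0; j < M; ++j) {
        double a = 0;
        for (int i = 0; i < M; ++i) a += alpha(t - 1, i) * trans(i, j);
        a *= B(t, j);
        alpha(t, j) = a;
        s += a;
      }
      if (s <= 0 || !R_FINITE(s)) {
        for (int j = 0; j < M; ++j) alpha(t, j) = 1.0 / M;
        s = DBL_MIN;
      } else {
        for (int j = 0; j < M; ++j) alpha(t, j) /= s;
      }
      scale[t] = s;
    }
    ll = 0;
    for (int t = 0; t < T; ++t) ll += std::log(scale[t]);

    if (R_FINITE(ll_prev) && ll < ll_prev - 1e-8 * (std::abs(ll_prev) + 1))
      decreased = true;
    if (R_FINITE(ll_prev) &&
        std::abs(ll - ll_prev) < tol * (std::abs(ll_prev) + DBL_EPSILON)) {
      converged = true;
      break;
    }
    if (n_iter >= max_iter) break;
    ll_prev = ll;
    ++n_iter;

    // backward
    for (int m = 0; m < M; ++m) beta(T - 1, m) = 1.0;
    for (int t = T - 2; t >= 0; --t)
      for (int i = 0; i < M; ++i) {
        double b = 0;
        for (int j = 0; j < M; ++j) b += trans(i, j) * B(t + 1, j) * beta(t + 1, j);
        beta(t, i) = b / scale[t + 1];
      }

    // posteriors
    for (int t = 0; t < T; ++t) {
      double g = 0;
      for (int m = 0; m < M; ++m) { gamma(t, m) = alpha(t, m) * beta(t, m); g += gamma(t, m); }
      if (g <= 0 || !R_FINITE(g)) {
        for (int m = 0; m < M; ++m) gamma(t, m) = alpha(t, m);
      } else {
        for (int m = 0; m < M; ++m) gamma(t, m) /= g;
      }
    }

    // transition update from expected counts
    if (T > 1) {
      NumericMatrix num(M, M);
      for (int t = 0; t < T - 1; ++t)
        for (int i = 0; i < M; ++i) {
          const double ai = alpha(t, i);
          for (int j = 0; j < M; ++j)
            num(i, j) += ai * trans(i, j) * B(t + 1, j) * beta(t + 1, j) / scale[t + 1];
        }
      for (int i = 0; i < M; ++i) {
        double denom = 0;
        for (int t = 0; t < T - 1; ++t) denom += gamma(t, i);
        double rs = 0;
        for (int j = 0; j < M; ++j) {
          trans(i, j) = num(i, j) / std::max(denom, DBL_MIN);
          rs += trans(i, j);
        }
        if (rs <= 0 || !R_FINITE(rs)) {
          for (int j = 0; j < M; ++j) trans(i, j) = 1.0 / M;
        } else {
          for (int j = 0; j < M; ++j) trans(i, j) /= rs;
        }
      }
    }

    // emission updates; a state with no posterior mass keeps its parameters
    for (int m = 0; m < M; ++m) {
      double w = 0, mu = 0;
      for (int t = 0; t < T; ++t) { w += gamma(t, m); mu += gamma(t, m) * x[t]; }
      if (w < 1e-12) continue;
      mu /= w;
      double v = 0;
      for (int t = 0; t < T; ++t) v += gamma(t, m) * (x[t] - mu) * (x[t] - mu);
      v /= w;
      if (!R_FINITE(v) || v < var_floor) { v = var_floor; floored = true; }
      if (!R_FINITE(mu)) mu = means[m];
      means[m] = mu;
      vars[m] = v;
    }
    for (int m = 0; m < M; ++m) init[m] = gamma(0, m);
  }

  return List::create(_["means"] = means, _["variances"] = vars,
                      _["transition"] = trans, _["initial"] = init,
                      _["loglik"] = ll, _["n_iter"] = n_iter,
                      _["converged"] = converged,
                      _["variance_floored"] = floored,
                      _["ll_decreased"] = decreased);
}
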