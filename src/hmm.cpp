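#include <Rcpp.h>
using namespace Rcpp;

static inline double dnorm_one(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
}

// Scaled forward-backward pass for a single gap-free observation sequence.
// Returns per-position posteriors (gamma), summed expected transition counts
// (xi_sum, 2x2), first-position posterior and the sequence log-likelihood.
// [[Rcpp::export(name = ".hmm_estep")]]
List hmm_estep(NumericVector y, NumericVector init, NumericMatrix trans,
               NumericVector mu, NumericVector sd) {
  const int T = y.size();
  NumericMatrix b(T, 2), alpha(T, 2), beta(T, 2), gamma(T, 2);
  NumericVector scale(T);
  for (int t = 0; t < T; ++t) {
    b(t, 0) = dnorm_one(y[t], mu[0], sd[0]);
    b(t, 1) = dnorm_one(y[t], mu[1], sd[1]);
  }
  // forward
  double c0 = 0.0;
  for (int i = 0; i < 2; ++i) { alpha(0, i) = init[i] * b(0, i); c0 += alpha(0, i); }
  if (c0 <= 0) c0 = 1e-300;
  for (int i = 0; i < 2; ++i) alpha(0, i) /= c0;
  scale[0] = c0;
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int j = 0; j < 2; ++j) {
      double a = alpha(t - 1, 0) * trans(0, j) + alpha(t - 1, 1) * trans(1, j);
      alpha(t, j) = a * b(t, j);
      ct += alpha(t, j);
    }
    if (ct <= 0) ct = 1e-300;
    for (int j = 0; j < 2; ++j) alpha(t, j) /= ct;
    scale[t] = ct;
  }
  // backward
  beta(T - 1, 0) = 1.0; beta(T - 1, 1) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < 2; ++i) {
      double s = 0.0;
      for (int j = 0; j < 2; ++j) s += trans(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / scale[t + 1];
    }
  }
  // posteriors and expected transitions
  NumericMatrix xi_sum(2, 2);
  for (int t = 0; t < T; ++t) {
    double norm = alpha(t, 0) * beta(t, 0) + alpha(t, 1) * beta(t, 1);
    if (norm <= 0) norm = 1e-300;
    for (int i = 0; i < 2; ++i) gamma(t, i) = alpha(t, i) * beta(t, i) / norm;
  }
  for (int t = 0; t < T - 1; ++t) {
    double denom = 0.0;
    double xi[2][2];
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) {
        xi[i][j] = alpha(t, i) * trans(i, j) * b(t + 1, j) * beta(t + 1, j);
        denom += xi[i][j];
      }
    if (denom <= 0) denom = 1e-300;
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) xi_sum(i, j) += xi[i][j] / denom;
  }
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(scale[t]);
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                      _["loglik"] = loglik);
}

// Viterbi decoding (log space) of a single gap-free sequence.
// Returns 1-based state indices.
// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(NumericVector y, NumericVector init,
                          NumericMatrix trans, NumericVector mu,
                          NumericVector sd) {
  const int T = y.size();
  NumericMatrix delta(T, 2);
  IntegerMatrix psi(T, 2);
  const double NEG = -1e300;
  auto lg = [](double v) { return v > 0 ? std::log(v) : -1e300; };
  for (int i = 0; i < 2; ++i)
    delta(0, i) = lg(init[i]) + lg(dnorm_one(y[0], mu[i], sd[i]));
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < 2; ++j) {
      double best = NEG; int arg = 0;
      for (int i = 0; i < 2; ++i) {
        double v = delta(t - 1, i) + lg(trans(i, j));
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + lg(dnorm_one(y[t], mu[j], sd[j]));
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  int last = delta(T - 1, 0) >= delta(T - 1, 1) ? 0 : 1;
  path[T - 1] = last + 1;
  for (int t = T - 2; t >= 0; --t) {
    last = psi(t + 1, last);
    path[t] = last + 1;
  }
  return path;
}
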