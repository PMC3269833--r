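#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One EM run for a two-component Gaussian mixture from a given parameter
// start. Log-likelihood is exact (natural log); variances are floored at
// vfloor to prevent component collapse on duplicated values. Returns the
// final parameters, the log-likelihood trace, and a convergence flag.
static List em_run(const NumericVector& x, double w, double mu1, double mu2,
                   double v1, double v2, double vfloor, double tol,
                   int max_iter) {
  const int n = x.size();
  std::vector<double> trace;
  trace.reserve(64);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false;
  const double wmin = 1e-12;

  std::vector<double> r2(n); // responsibility of component 2
  for (int iter = 0; iter < max_iter; ++iter) {
    // E-step + log-likelihood
    double lw1 = std::log(std::max(1.0 - w, wmin));
    double lw2 = std::log(std::max(w, wmin));
    double c1 = lw1 - 0.5 * std::log(2.0 * M_PI * v1);
    double c2 = lw2 - 0.5 * std::log(2.0 * M_PI * v2);
    double iv1 = 0.5 / v1, iv2 = 0.5 / v2;
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double d1 = x[i] - mu1, d2 = x[i] - mu2;
      double l1 = c1 - d1 * d1 * iv1;
      double l2 = c2 - d2 * d2 * iv2;
      // logsumexp with a single exp: e = exp(-|l1 - l2|) <= 1
      if (l1 >= l2) {
        double e = std::exp(l2 - l1);
        ll += l1 + std::log1p(e);
        r2[i] = e / (1.0 + e);
      } else {
        double e = std::exp(l1 - l2);
        ll += l2 + std::log1p(e);
        r2[i] = 1.0 / (1.0 + e);
      }
    }
    trace.push_back(ll);
    if (iter > 0 && std::fabs(ll - ll_old) < tol) {
      converged = true;
      break;
    }
    ll_old = ll;
    // M-step
    double n2 = 0.0, s2 = 0.0, s1 = 0.0;
    for (int i = 0; i < n; ++i) {
      n2 += r2[i];
      s2 += r2[i] * x[i];
      s1 += (1.0 - r2[i]) * x[i];
    }
    double n1 = n - n2;
    if (n2 < wmin * n) n2 = wmin * n;
    if (n1 < wmin * n) n1 = wmin * n;
    w = n2 / n;
    mu2 = s2 / n2;
    mu1 = s1 / n1;
    double q1 = 0.0, q2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double d1 = x[i] - mu1, d2 = x[i] - mu2;
      q1 += (1.0 - r2[i]) * d1 * d1;
      q2 += r2[i] * d2 * d2;
    }
    v1 = std::max(q1 / n1, vfloor);
    v2 = std::max(q2 / n2, vfloor);
  }
  return List::create(_["w2"] = w, _["mu1"] = mu1, _["mu2"] = mu2,
                      _["v1"] = v1, _["v2"] = v2, _["loglik"] = ll,
                      _["converged"] = converged,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// [[Rcpp::export]]
List em_two_gaussian_cpp(NumericVector x, NumericMatrix starts, double vfloor,
                         double tol, int max_iter) {
  // starts: one row per restart, columns (w2, mu1, mu2, v1, v2)
  List best;
  double best_ll = R_NegInf;
  int n_starts = starts.nrow();
  bool any_converged = false;
  for (int s = 0; s < n_starts; ++s) {
    List fit = em_run(x, starts(s, 0), starts(s, 1), starts(s, 2),
                      std::max(starts(s, 3), vfloor),
                      std::max(starts(s, 4), vfloor), vfloor, tol, max_iter);
    if (as<bool>(fit["converged"])) any_converged = true;
    double ll = as<double>(fit["loglik"]);
    if (ll > best_ll) {
      best_ll = ll;
      best = fit;
    }
  }
  best["any_converged"] = any_converged;
  return best;
}

// [[Rcpp::export]]
NumericVector posterior_high_cpp(NumericVector x, double w2, double mu1,
                                 double mu2, double v1, double v2) {
  // posterior responsibility of the higher-mean component (component 2 after
  // sorting in R)
  int n = x.size();
  NumericVector out(n);
  double lw1 = std::log(std::max(1.0 - w2, 1e-300));
  double lw2 = std::log(std::max(w2, 1e-300));
  double c1 = -0.5 * std::log(2.0 * M_PI * v1);
  double c2 = -0.5 * std::log(2.0 * M_PI * v2);
  for (int i = 0; i < n; ++i) {
    double d1 = x[i] - mu1, d2 = x[i] - mu2;
    double l1 = lw1 + c1 - d1 * d1 / (2.0 * v1);
    double l2 = lw2 + c2 - d2 * d2 / (2.0 * v2);
    double m = l1 > l2 ? l1 : l2;
    out[i] = std::exp(l2 - m) / (std::exp(l1 - m) + std::exp(l2 - m));
  }
  return out;
}
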