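#include <Rcpp.h>
using namespace Rcpp;

// Overflow-safe logistic
static inline double logistic(double t) {
  if (t >= 0.0) return 1.0 / (1.0 + std::exp(-t));
  double e = std::exp(t);
  return e / (1.0 + e);
}

// Posterior-mode update equation for one step of the mixed filter:
// g(x) = x - x_pred - var_pred * [ (beta/var_eps) (v - alpha - beta x)
//                                  + (lam - logistic(mu + x)) ].
// g is strictly increasing (g' >= 1), so the root is unique.
static inline double g_fun(double x, double x_pred, double var_pred,
                           double v, double lam, double rho, double alpha,
                           double beta, double var_eps, double mu) {
  (void)rho;
  return x - x_pred -
         var_pred * ((beta / var_eps) * (v - alpha - beta * x) +
                     (lam - logistic(mu + x)));
}

// [[Rcpp::export]]
List mixed_forward_cpp(NumericVector v, NumericVector lam, double rho,
                       double alpha, double beta, double var_eta,
                       double var_eps, double mu, double x0, double var0) {
  const int K = v.size();
  NumericVector x_pred(K), var_pred(K), x_filt(K), var_filt(K), p(K);
  const double eps = 2.220446049250313e-16;
  double xp = x0, vp = var0;

  for (int k = 0; k < K; ++k) {
    const double xpr = rho * xp;
    const double vpr = rho * rho * vp + var_eta;
    x_pred[k] = xpr;
    var_pred[k] = vpr;

    // Newton-Raphson on g(x) = 0, started at the prediction
    double x = xpr;
    bool converged = false;
    for (int it = 0; it < 50; ++it) {
      const double pk = logistic(mu + x);
      const double g = x - xpr -
          vpr * ((beta / var_eps) * (v[k] - alpha - beta * x) + (lam[k] - pk));
      const double gp = 1.0 + vpr * (beta * beta / var_eps + pk * (1.0 - pk));
      const double step = g / gp;
      x -= step;
      if (std::fabs(step) < 1e-12 * (1.0 + std::fabs(x))) {
        converged = true;
        break;
      }
    }
    if (!converged || !std::isfinite(x)) {
      // bisection fallback on an expanding bracket
      double lo = xpr - 1.0, hi = xpr + 1.0;
      double glo = g_fun(lo, xpr, vpr, v[k], lam[k], rho, alpha, beta, var_eps, mu);
      double ghi = g_fun(hi, xpr, vpr, v[k], lam[k], rho, alpha, beta, var_eps, mu);
      int grow = 0;
      while (glo * ghi > 0.0 && grow < 200) {
        lo -= (hi - lo);
        hi += (hi - lo);
        glo = g_fun(lo, xpr, vpr, v[k], lam[k], rho, alpha, beta, var_eps, mu);
        ghi = g_fun(hi, xpr, vpr, v[k], lam[k], rho, alpha, beta, var_eps, mu);
        ++grow;
      }
      if (glo * ghi > 0.0)
        stop("mixed filter update failed to bracket a root at step %d", k + 1);
      for (int it = 0; it < 200; ++it) {
        const double mid = 0.5 * (lo + hi);
        const double gm = g_fun(mid, xpr, vpr, v[k], lam[k], rho, alpha, beta,
                                var_eps, mu);
        if (gm > 0.0) hi = mid; else lo = mid;
        if (hi - lo < 1e-12 * (1.0 + std::fabs(mid))) break;
      }
      x = 0.5 * (lo + hi);
      if (!std::isfinite(x))
        stop("mixed filter update did not converge at step %d", k + 1);
    }

    double pk = logistic(mu + x);
    if (pk < eps) pk = eps;
    if (pk > 1.0 - eps) pk = 1.0 - eps;
    const double vf = 1.0 /
        (1.0 / vpr + beta * beta / var_eps + pk * (1.0 - pk));
    x_filt[k] = x;
    var_filt[k] = vf;
    p[k] = pk;
    xp = x;
    vp = vf;
  }

  return List::create(_["x_pred"] = x_pred, _["var_pred"] = var_pred,
                      _["x_filt"] = x_filt, _["var_filt"] = var_filt,
                      _["p"] = p);
}

// Fixed-interval (RTS-form) smoother for the mixed filter output.
// s_k = rho * var_filt_k / var_pred_{k+1}; returns the smoothing gains
// as well, since the EM M-step needs the lag-one smoothed covariance
// cov(x_k, x_{k+1} | K) = s_k * var_smooth_{k+1}.
// [[Rcpp::export]]
List mixed_smooth_cpp(NumericVector x_filt, NumericVector var_filt,
                      NumericVector x_pred, NumericVector var_pred,
                      double rho) {
  const int K = x_filt.size();
  NumericVector x_sm(K), var_sm(K), gain(K);
  x_sm[K - 1] = x_filt[K - 1];
  var_sm[K - 1] = var_filt[K - 1];
  gain[K - 1] = NA_REAL;
  for (int k = K - 2; k >= 0; --k) {
    const double s = rho * var_filt[k] / var_pred[k + 1];
    x_sm[k] = x_filt[k] + s * (x_sm[k + 1] - x_pred[k + 1]);
    var_sm[k] = var_filt[k] + s * s * (var_sm[k + 1] - var_pred[k + 1]);
    gain[k] = s;
  }
  return List::create(_["x_smooth"] = x_sm, _["var_smooth"] = var_sm,
                      _["gain"] = gain);
}
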