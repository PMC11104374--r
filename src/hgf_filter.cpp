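#include <Rcpp.h>
using namespace Rcpp;

// Binary 3-level HGF, one-step variational updates folded over a trial
// sequence. Level 1: advice accuracy (Bernoulli), level 2: adviser fidelity
// tendency (Gaussian random walk with volatility exp(kappa2*x3 + omega2)),
// level 3: log-volatility (random walk; optionally mean-reverting towards
// m3 at rate phi3).
//
// Returns a matrix with one row per trial. A parameter vector is "invalid"
// when a post-update precision is non-positive; the first failing trial is
// reported in the "valid_until" attribute and rows from there on are NA.
//
// Column layout (keep in sync with hgf_filter() in R/hgf.R):
// 0 muhat1, 1 pihat1, 2 muhat2, 3 pihat2, 4 muhat3, 5 pihat3,
// 6 mu2, 7 sigma2, 8 mu3, 9 sigma3, 10 delta1, 11 delta2,
// 12 v2, 13 w2, 14 lr1

// [[Rcpp::export]]
NumericMatrix hgf_filter_cpp(IntegerVector u,
                             double kappa2, double omega2, double theta,
                             double mu2_0, double sigma2_0,
                             double mu3_0, double sigma3_0,
                             double m3, double phi3,
                             bool mean_reverting) {
  const int n = u.size();
  NumericMatrix out(n, 15);
  std::fill(out.begin(), out.end(), NA_REAL);

  double mu2 = mu2_0, sigma2 = sigma2_0;
  double mu3 = mu3_0, sigma3 = sigma3_0;
  int valid_until = n; // trials 1..valid_until have finite rows

  for (int k = 0; k < n; ++k) {
    // predictions
    const double muhat2 = mu2;
    const double muhat3 = mean_reverting ? mu3 + phi3 * (m3 - mu3) : mu3;
    // clamp away from {0,1} so pihat1 and the response model stay finite
    // when the tendency belief saturates the sigmoid in double precision
    double muhat1 = 1.0 / (1.0 + std::exp(-muhat2));
    muhat1 = std::min(std::max(muhat1, 1e-15), 1.0 - 1e-15);
    const double pihat1 = 1.0 / (muhat1 * (1.0 - muhat1));

    // level-2 update; v2 uses the pre-drift mu3 (previous posterior)
    const double v2 = std::exp(kappa2 * mu3 + omega2);
    const double pihat2 = 1.0 / (sigma2 + v2);
    const double delta1 = (double)u[k] - muhat1;
    const double pi2 = pihat2 + muhat1 * (1.0 - muhat1);
    const double mu2_new = muhat2 + delta1 / pi2;
    const double sigma2_new = 1.0 / pi2;

    // level-3 update
    const double pihat3 = 1.0 / (sigma3 + theta);
    const double w2 = v2 * pihat2;
    const double delta2 =
      (sigma2_new + (mu2_new - muhat2) * (mu2_new - muhat2)) * pihat2 - 1.0;
    const double pi3 =
      pihat3 + 0.5 * kappa2 * kappa2 * w2 * (w2 + (2.0 * w2 - 1.0) * delta2);

    if (!(pi2 > 0.0) || !(pi3 > 0.0) || !std::isfinite(pi3)) {
      valid_until = k; // 0-based count of completed trials
      break;
    }

    const double mu3_new = muhat3 + 0.5 * kappa2 * (w2 / pi3) * delta2;
    const double sigma3_new = 1.0 / pi3;

    out(k, 0) = muhat1;  out(k, 1) = pihat1;
    out(k, 2) = muhat2;  out(k, 3) = pihat2;
    out(k, 4) = muhat3;  out(k, 5) = pihat3;
    out(k, 6) = mu2_new; out(k, 7) = sigma2_new;
    out(k, 8) = mu3_new; out(k, 9) = sigma3_new;
    out(k, 10) = delta1; out(k, 11) = delta2;
    out(k, 12) = v2;     out(k, 13) = w2;
    out(k, 14) = pihat1 / pi2;

    mu2 = mu2_new; sigma2 = sigma2_new;
    mu3 = mu3_new; sigma3 = sigma3_new;
  }

  out.attr("valid_until") = valid_until;
  return out;
}
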