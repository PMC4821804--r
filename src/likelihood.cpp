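#include <Rcpp.h>
using namespace Rcpp;

// numerically stable log(1 + exp(x)) (softplus)
static inline double softplus(double x) {
  if (x > 700.0) return x;
  return std::log1p(std::exp(x));
}

// Joint negative log-likelihood of observed choices and confidence
// reports under the confidence-guided learning model, run in conditioned
// mode: per trial the decision value is computed from the current
// weights, the choice and (censored-Gaussian) confidence likelihoods are
// accumulated, and then the observed choice/confidence drive the
// associative weight update and the expected-confidence update.
//
// choice_cw: 1 = clockwise, 0 = counterclockwise.
// cbar_first: if true the expected-confidence update precedes the weight
// update within a trial (prediction error then recomputed).
// [[Rcpp::export]]
double cl_nll_conditioned(NumericVector E_ccw, NumericVector E_cw,
                          IntegerVector choice_cw, NumericVector confidence,
                          double alpha_w, double alpha_c, double beta,
                          double lambda, double sigma_c,
                          double w0_signal, double w0_noise,
                          double c_bar0, bool cbar_first) {
  const int n = E_ccw.size();
  if (E_cw.size() != n || choice_cw.size() != n || confidence.size() != n)
    stop("Energy, choice and confidence vectors must have equal length.");
  if (sigma_c <= 0.0) stop("`sigma_c` must be > 0.");

  double w_ccw_ccw = w0_signal, w_cw_cw = w0_signal;
  double w_ccw_cw = w0_noise, w_cw_ccw = w0_noise;
  double c_bar = c_bar0;
  const double log_floor = std::log(1e-300);
  double ll = 0.0;

  for (int t = 0; t < n; ++t) {
    const double ecc = E_ccw[t], ecw = E_cw[t];
    const double A_ccw = ecc * w_ccw_ccw + ecw * w_cw_ccw;
    const double A_cw = ecw * w_cw_cw + ecc * w_ccw_cw;
    const double dv = A_cw - A_ccw;

    // choice term: softmax on beta * DV
    const double z = beta * dv;
    ll += (choice_cw[t] == 1) ? -softplus(-z) : -softplus(z);

    // confidence term: Gaussian around decisional certainty, censored at
    // the ends of the rating scale
    const double cert = lambda * std::fabs(dv);
    const double c = confidence[t];
    double lc;
    if (c <= 0.0) {
      lc = R::pnorm(0.0, cert, sigma_c, 1, 1);
    } else if (c >= 1.0) {
      lc = R::pnorm(1.0, cert, sigma_c, 0, 1);
    } else {
      lc = R::dnorm(c, cert, sigma_c, 1);
    }
    if (lc < log_floor) lc = log_floor;
    ll += lc;

    // learning updates driven by the observed reports
    double delta;
    if (cbar_first) {
      c_bar += alpha_c * (c - c_bar);
      delta = c - c_bar;
    } else {
      delta = c - c_bar;
    }
    const double A_choice = (choice_cw[t] == 1) ? A_cw : A_ccw;
    const double g = alpha_w * delta * A_choice;
    if (choice_cw[t] == 1) {
      w_cw_cw += g * ecw;
      w_ccw_cw += g * ecc;
    } else {
      w_ccw_ccw += g * ecc;
      w_cw_ccw += g * ecw;
    }
    if (!cbar_first) c_bar += alpha_c * delta;
  }

  if (!std::isfinite(ll)) return 1e10;
  return -ll;
}
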