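#include <Rcpp.h>
using namespace Rcpp;

// Per-trial loop of the hybrid memory-sampling + TD choice model.
//
// The memory sampler weights each past outcome of a deck by the recency
// kernel a_s * (1 - a_s)^(t - i), renormalized over that deck's own choice
// history. Relative weights among a deck's samples do not depend on the
// current trial t, so each deck carries an unnormalized numerator and
// denominator expressed in units of its most recent sample's weight:
// when the deck is chosen again after a gap g, both are scaled by
// (1 - a_s)^g before the new outcome is appended. This reproduces the
// enumerated expectation exactly (including the a_s -> 1 limit, where all
// weight falls on the most recent sample) in O(1) per trial.
//
// choice: 1..3, NA = missing response (contributes nothing, advances no
// learner, and clears the perseveration indicator). reward: 0/1.

static inline void softmax3(const double *logit, double *p) {
  double m = logit[0];
  if (logit[1] > m) m = logit[1];
  if (logit[2] > m) m = logit[2];
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    p[k] = std::exp(logit[k] - m);
    s += p[k];
  }
  for (int k = 0; k < 3; ++k) p[k] /= s;
}

// [[Rcpp::export(name = ".hybrid_loglik_cpp")]]
double hybrid_loglik_cpp(IntegerVector choice, IntegerVector reward,
                         double a_rl, double a_s,
                         double b_rl, double b_s, double b_p) {
  const int n = choice.size();
  double v_rl[3] = {0.0, 0.0, 0.0};   // TD values, initialized to zero
  double num[3] = {0.0, 0.0, 0.0};    // sampler numerators
  double den[3] = {0.0, 0.0, 0.0};    // sampler denominators
  int last[3] = {-1, -1, -1};         // trial of each deck's last choice
  int prev = -1;                      // previous chosen deck, -1 = none
  const double om = 1.0 - a_s;
  double ll = 0.0;

  for (int t = 0; t < n; ++t) {
    if (choice[t] == NA_INTEGER) {
      prev = -1;
      continue;
    }
    double logit[3], p[3];
    for (int k = 0; k < 3; ++k) {
      double vs = (den[k] > 0.0) ? num[k] / den[k] : 0.0;
      logit[k] = b_rl * v_rl[k] + b_s * vs + ((prev == k) ? b_p : 0.0);
    }
    softmax3(logit, p);
    const int c = choice[t] - 1;
    ll += std::log(p[c]);

    const double r = (double) reward[t];
    v_rl[c] += a_rl * (r - v_rl[c]);
    if (last[c] < 0) {
      num[c] = r;
      den[c] = 1.0;
    } else {
      const double decay = std::pow(om, (double) (t - last[c]));
      num[c] = num[c] * decay + r;
      den[c] = den[c] * decay + 1.0;
    }
    last[c] = t;
    prev = c;
  }
  return ll;
}

// Same recursion, returning the model's per-trial choice probabilities
// (rows for missing-response trials hold the pre-update probabilities).

// [[Rcpp::export(name = ".hybrid_trial_probs_cpp")]]
NumericMatrix hybrid_trial_probs_cpp(IntegerVector choice, IntegerVector reward,
                                     double a_rl, double a_s,
                                     double b_rl, double b_s, double b_p) {
  const int n = choice.size();
  NumericMatrix P(n, 3);
  double v_rl[3] = {0.0, 0.0, 0.0};
  double num[3] = {0.0, 0.0, 0.0};
  double den[3] = {0.0, 0.0, 0.0};
  int last[3] = {-1, -1, -1};
  int prev = -1;
  const double om = 1.0 - a_s;

  for (int t = 0; t < n; ++t) {
    double logit[3], p[3];
    for (int k = 0; k < 3; ++k) {
      double vs = (den[k] > 0.0) ? num[k] / den[k] : 0.0;
      logit[k] = b_rl * v_rl[k] + b_s * vs + ((prev == k) ? b_p : 0.0);
    }
    softmax3(logit, p);
    for (int k = 0; k < 3; ++k) P(t, k) = p[k];
    if (choice[t] == NA_INTEGER) {
      prev = -1;
      continue;
    }
    const int c = choice[t] - 1;
    const double r = (double) reward[t];
    v_rl[c] += a_rl * (r - v_rl[c]);
    if (last[c] < 0) {
      num[c] = r;
      den[c] = 1.0;
    } else {
      const double decay = std::pow(om, (double) (t - last[c]));
      num[c] = num[c] * decay + r;
      den[c] = den[c] * decay + 1.0;
    }
    last[c] = t;
    prev = c;
  }
  return P;
}
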