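#include <Rcpp.h>
using namespace Rcpp;

// log of the logistic function, overflow-safe
static inline double log_logistic(double x) {
  if (x > 0.0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

// Replay negative log-likelihood of the hybrid instrumental/Pavlovian learner
// over a set of subject-block segments.
//
// Each segment is one subject-block: stimulus values V and action values Q
// start at zero (new cards per block) and are updated by the delta rule on
// every trial. The choice rule is a two-option softmax on weights
//   W(Go)   = Q(Go|s) + b_go + pi * V(s)
//   W(NoGo) = Q(NoGo|s)
// divided by the temperature beta, so larger beta means more random choice.
//
// card: 1..4 card index; go: 1 for a Go response; reward: scaled feedback the
// learner saw (Go-cost included). start/end are 1-based inclusive indices into
// the trial vectors; alpha/beta/pi/bgo are natural-scale parameters, one per
// segment. Returns the NLL of each segment.
// [[Rcpp::export]]
NumericVector gng_nll_segments(IntegerVector card, IntegerVector go,
                               NumericVector reward,
                               IntegerVector start, IntegerVector end,
                               NumericVector alpha, NumericVector beta,
                               NumericVector pi, NumericVector bgo) {
  const int nseg = start.size();
  NumericVector out(nseg);
  for (int s = 0; s < nseg; ++s) {
    double V[4]  = {0.0, 0.0, 0.0, 0.0};
    double Qg[4] = {0.0, 0.0, 0.0, 0.0};
    double Qn[4] = {0.0, 0.0, 0.0, 0.0};
    const double a = alpha[s], b = beta[s], p = pi[s], bg = bgo[s];
    double nll = 0.0;
    for (int t = start[s] - 1; t < end[s]; ++t) {
      const int c = card[t] - 1;
      const double x = (Qg[c] + bg + p * V[c] - Qn[c]) / b;
      nll -= (go[t] == 1) ? log_logistic(x) : log_logistic(-x);
      const double r = reward[t];
      V[c] += a * (r - V[c]);
      if (go[t] == 1) Qg[c] += a * (r - Qg[c]);
      else            Qn[c] += a * (r - Qn[c]);
    }
    out[s] = nll;
  }
  return out;
}
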