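#include <Rcpp.h>
using namespace Rcpp;

// Max-product decoding in log space over a small dense state space.
// obs holds 0-based emission column indices; ties break toward the lower
// state index at every argmax so the normal state is preferred.
// [[Rcpp::export]]
List viterbi_cpp(NumericVector log_initial,
                 NumericMatrix log_transition,
                 NumericMatrix log_emission,
                 IntegerVector obs) {
  const int S = log_initial.size();
  const int n = obs.size();

  if (n == 0) {
    return List::create(_["path"] = IntegerVector(0),
                        _["log_joint"] = 0.0);
  }

  NumericVector delta(S), delta_new(S);
  IntegerMatrix back(n, S);

  for (int s = 0; s < S; ++s)
    delta[s] = log_initial[s] + log_emission(s, obs[0]);

  for (int t = 1; t < n; ++t) {
    const int o = obs[t];
    for (int j = 0; j < S; ++j) {
      double best = delta[0] + log_transition(0, j);
      int arg = 0;
      for (int i = 1; i < S; ++i) {
        const double cand = delta[i] + log_transition(i, j);
        if (cand > best) { best = cand; arg = i; }
      }
      delta_new[j] = best + log_emission(j, o);
      back(t, j) = arg;
    }
    for (int s = 0; s < S; ++s) delta[s] = delta_new[s];
  }

  int last = 0;
  for (int s = 1; s < S; ++s)
    if (delta[s] > delta[last]) last = s;

  IntegerVector path(n);
  path[n - 1] = last;
  for (int t = n - 1; t > 0; --t)
    path[t - 1] = back(t, path[t]);

  return List::create(_["path"] = path,
                      _["log_joint"] = delta[last]);
}
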