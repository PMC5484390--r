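#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo core: repeated single decisions of the preference layer.
//
// `aw` holds the already-weighted sublayer equilibria (w_j * alpha_ij) for
// the considered alternatives only (n rows, M columns). Each step draws one
// attribute from `cum_probs` (cumulative sampling distribution), updates all
// preference nodes synchronously through the bounded piecewise-linear
// activation, and stops at the first step where any node reaches Q
// (inclusive). Simultaneous crossings are broken uniformly at random.
// Decisions still running at T_max are censored (chosen = NA).
//
// Uses R's RNG (one uniform per step for the attribute, one extra uniform
// only when several nodes cross together), so results are reproducible under
// set.seed() and the pure-R mirror consumes an identical stream.

// [[Rcpp::export]]
List sim_choices_cpp(NumericMatrix aw, double s_P, double l_P, double Q,
                     int T_max, NumericVector cum_probs, int n_reps) {
  const int n = aw.nrow();
  const int M = aw.ncol();
  IntegerVector chosen(n_reps);
  IntegerVector dtime(n_reps);
  std::vector<double> x(n), xn(n);
  std::vector<int> crossers(n);

  for (int r = 0; r < n_reps; ++r) {
    std::fill(x.begin(), x.end(), 0.0);
    int ch = NA_INTEGER;
    int t_done = T_max;
    for (int t = 1; t <= T_max; ++t) {
      double u = unif_rand();
      int j = 0;
      while (j < M - 1 && u >= cum_probs[j]) ++j;
      double S = 0.0;
      for (int i = 0; i < n; ++i) S += x[i];
      int k = 0;
      for (int i = 0; i < n; ++i) {
        double v = s_P * x[i] - l_P * (S - x[i]) + aw(i, j);
        if (v > 1.0) v = 1.0; else if (v < 0.0) v = 0.0;
        xn[i] = v;
        if (v >= Q) crossers[k++] = i;
      }
      if (k > 0) {
        int pick = crossers[0];
        if (k > 1) {
          int idx = static_cast<int>(unif_rand() * k);
          if (idx >= k) idx = k - 1;
          pick = crossers[idx];
        }
        ch = pick + 1;
        t_done = t;
        break;
      }
      x.swap(xn);
    }
    chosen[r] = ch;
    dtime[r] = t_done;
  }
  return List::create(_["chosen"] = chosen, _["time"] = dtime);
}
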