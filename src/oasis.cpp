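#include <Rcpp.h>
#include <vector>

// Online pool-adjacent-violators solver for sparse non-negative AR(1)
// deconvolution:
//
//   minimize 0.5 * ||y - c||^2 + lambda * sum_t s_t
//   subject to s_t = c_t - gamma * c_{t-1} >= 0   (c_0 = 0)
//
// The l1 term is absorbed into the target: sum_t s_t equals
// sum_{t<T} (1 - gamma) c_t + c_T, so the problem is an isotonic-type
// regression of c against y_t - lambda * mu_t with mu_t = 1 - gamma for
// t < T and mu_T = 1. Each pool stores the running numerator/denominator of
// its height; pools are merged while the decay constraint between adjacent
// pools is violated, and negative pool heights are floored at zero when the
// solution is read out.
// [[Rcpp::export]]
Rcpp::NumericVector oasis_ar1(Rcpp::NumericVector y, double gamma, double lambda) {
  const int T = y.size();
  Rcpp::NumericVector c(T);
  if (T == 0) return c;

  std::vector<double> num(T), den(T), val(T);
  std::vector<int> start(T), len(T);
  int np = 0; // number of pools

  for (int t = 0; t < T; ++t) {
    double mu = (t == T - 1) ? 1.0 : (1.0 - gamma);
    double yt = y[t] - lambda * mu;
    num[np] = yt;
    den[np] = 1.0;
    val[np] = yt;
    start[np] = t;
    len[np] = 1;
    ++np;
    while (np > 1) {
      double g = std::pow(gamma, (double)len[np - 2]);
      if (val[np - 1] >= g * val[np - 2]) break;
      // merge the last two pools
      num[np - 2] += g * num[np - 1];
      den[np - 2] += g * g * den[np - 1];
      len[np - 2] += len[np - 1];
      val[np - 2] = num[np - 2] / den[np - 2];
      --np;
    }
  }

  for (int i = 0; i < np; ++i) {
    double v = val[i] > 0.0 ? val[i] : 0.0;
    for (int k = 0; k < len[i]; ++k) {
      c[start[i] + k] = v;
      v *= gamma;
    }
  }
  return c;
}
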