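#include <Rcpp.h>
using namespace Rcpp;

// Batch decision stage for the population models.
//
// Each simulated trial i has a combined population response over K channels:
//   M[k, i] = a * st[k] + b * sf[k] + c * E[k, i] + d * L[k, i]
// where st/sf are the noiseless target/flanker tuning profiles and E/L are
// pre-smoothed unit-SD noise fields (one column per trial). Returns the
// 1-based index of the maximal channel per trial; exact ties are broken
// uniformly at random (reservoir sampling over the tied set).
//
// Passing a 0-column matrix for E or L drops that noise source, so the same
// kernel serves the pooling model, the noise-only model and noiseless runs.

// [[Rcpp::export]]
IntegerVector decide_pool_batch(NumericVector st, NumericVector sf,
                                NumericMatrix E, NumericMatrix L,
                                double a, double b, double c, double d,
                                int n_trials) {
  const int K = st.size();
  if (sf.size() != K) stop("target and flanker profiles differ in length");
  const bool useE = E.ncol() > 0, useL = L.ncol() > 0;
  if (useE && (E.nrow() != K || E.ncol() < n_trials))
    stop("early-noise field has wrong dimensions");
  if (useL && (L.nrow() != K || L.ncol() < n_trials))
    stop("late-noise field has wrong dimensions");

  IntegerVector out(n_trials);
  std::vector<double> base(K);
  for (int k = 0; k < K; ++k) base[k] = a * st[k] + b * sf[k];
  const double *pe = useE ? &E(0, 0) : nullptr;
  const double *pl = useL ? &L(0, 0) : nullptr;

  for (int i = 0; i < n_trials; ++i) {
    const double *ei = useE ? pe + (size_t)i * K : nullptr;
    const double *li = useL ? pl + (size_t)i * K : nullptr;
    double best = R_NegInf;
    int arg = 0, nties = 1;
    for (int k = 0; k < K; ++k) {
      double v = base[k];
      if (ei) v += c * ei[k];
      if (li) v += d * li[k];
      if (v > best) {
        best = v; arg = k; nties = 1;
      } else if (v == best) {
        ++nties;
        if (unif_rand() * nties < 1.0) arg = k;
      }
    }
    if (!R_finite(best)) stop("non-finite population response");
    out[i] = arg + 1;
  }
  return out;
}
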