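#include <Rcpp.h>
using namespace Rcpp;

// One coordinate-ascent sweep over the penalized features of a
// spike-and-slab variational regression.
//
// W      n x P penalized design (mean-centered)
// d      column squared norms of W
// r      length-n residual  y - mu - T alpha - sum_j p_j mu_j w_j
//        (updated in place)
// pj, mu, s2  per-feature variational factors (updated in place)
// ee     E[sigma_e^{-2}],  eb  E[sigma_beta^{-2}]
// elogb  E[log sigma_beta^{-2}] (the exact update of the inclusion odds
//        requires the log-moment, not log of the mean)
// logodds  E[log pi - log(1 - pi)] under the truncated-Beta factor
// ord    0-based update order for this sweep
// active features flagged false (zero-variance columns) are skipped
// [[Rcpp::export]]
List vb_sweep_cpp(const NumericMatrix& W, const NumericVector& d,
                  NumericVector r, NumericVector pj, NumericVector mu,
                  NumericVector s2, double ee, double eb, double elogb,
                  double logodds,
                  const IntegerVector& ord, const LogicalVector& active) {
  const int n = W.nrow();
  for (int k = 0; k < ord.size(); ++k) {
    const int j = ord[k];
    if (!active[j]) continue;
    const double* wj = &W(0, j);
    const double old_contrib = pj[j] * mu[j];
    // r currently excludes nothing; add feature j's expected fit back in
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += wj[i] * r[i];
    dot += old_contrib * d[j];  // w_j' r_{-j}
    const double s2j = 1.0 / (ee * d[j] + eb);
    const double muj = ee * s2j * dot;
    const double z = logodds + 0.5 * (elogb + std::log(s2j)) +
      muj * muj / (2.0 * s2j);
    double p;
    if (z > 0) p = 1.0 / (1.0 + std::exp(-z));
    else { const double e = std::exp(z); p = e / (1.0 + e); }
    if (!std::isfinite(muj) || !std::isfinite(p))
      stop("non-finite variational update at feature %d", j + 1);
    const double delta = old_contrib - p * muj;
    if (delta != 0.0)
      for (int i = 0; i < n; ++i) r[i] += delta * wj[i];
    pj[j] = p; mu[j] = muj; s2[j] = s2j;
  }
  return List::create(_["r"] = r, _["p"] = pj, _["mu"] = mu,
                      _["s2"] = s2);
}
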