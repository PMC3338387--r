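#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-descent core in covariance (Gram) form for
//   min_beta  (2n)^{-1} ||y - X beta||^2 + lambda * sum_j pf_j |beta_j|
// with X column-standardized (G_jj = n).  Uses the active-set strategy:
// full sweeps over all coordinates alternate with cheap sweeps over the
// current active set until a full sweep changes nothing.
namespace {

inline double soft(double num, double thr) {
  if (num > thr) return num - thr;
  if (num < -thr) return num + thr;
  return 0.0;
}

// one coordinate update; returns |change|
inline double cd_update(int j, const double* c, const double* G, int p,
                        double n, double lam, const double* pf,
                        double* b, double* v) {
  const double num = (c[j] - v[j]) / n + b[j];
  const double bn = soft(num, lam * pf[j]);
  const double diff = bn - b[j];
  if (diff != 0.0) {
    const double* gj = G + static_cast<size_t>(j) * p;
    for (int i = 0; i < p; ++i) v[i] += diff * gj[i];
    b[j] = bn;
  }
  return std::fabs(diff);
}

// solve at one lambda (warm start in b, v = G b); returns iterations
int cd_solve(const double* c, const double* G, int p, double n,
             double lam, const double* pf, double tol, int max_iter,
             double* b, double* v, std::vector<int>& active) {
  int it = 0;
  while (it < max_iter) {
    // full sweep; rebuild the active set
    ++it;
    double maxdiff = 0.0;
    active.clear();
    for (int j = 0; j < p; ++j) {
      if (!std::isfinite(pf[j])) continue;
      const double d = cd_update(j, c, G, p, n, lam, pf, b, v);
      if (d > maxdiff) maxdiff = d;
      if (b[j] != 0.0) active.push_back(j);
    }
    if (maxdiff < tol) break;
    // active-set sweeps until stable
    while (it < max_iter) {
      ++it;
      double md = 0.0;
      for (size_t k = 0; k < active.size(); ++k) {
        const double d = cd_update(active[k], c, G, p, n, lam, pf, b, v);
        if (d > md) md = d;
      }
      if (md < tol) break;
    }
  }
  return it;
}

}  // namespace

// Lasso path over a decreasing lambda sequence with warm starts.
//
// If max_active >= 0, the path stops as soon as a solution has more
// than max_active nonzero coefficients (the remaining, smaller lambdas
// keep that solution and are flagged in `truncated`); callers that only
// need the sparse end of the path use this to skip the saturated
// region.
//
// Returns the P x L coefficient matrix, the KKT residual per lambda,
// the active count per lambda and the truncation flags.
// [[Rcpp::export]]
List lasso_path_gram(const NumericMatrix& G, const NumericVector& c,
                     double n, const NumericVector& lambdas,
                     const NumericVector& pf, double tol, int max_iter,
                     int max_active = -1) {
  const int P = G.ncol();
  const int L = lambdas.size();
  NumericMatrix beta(P, L);
  NumericVector kkt(L);
  IntegerVector nact(L);
  LogicalVector truncated(L);
  std::vector<double> b(P, 0.0), v(P, 0.0);
  std::vector<int> active;

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    cd_solve(&c[0], &G(0, 0), P, n, lam, &pf[0], tol, max_iter,
             b.data(), v.data(), active);
    // KKT residual: max violation of the subgradient conditions
    double viol = 0.0;
    for (int j = 0; j < P; ++j) {
      if (!std::isfinite(pf[j])) continue;
      const double g = (c[j] - v[j]) / n;
      const double thr = lam * pf[j];
      double w;
      if (b[j] > 0) w = std::fabs(g - thr);
      else if (b[j] < 0) w = std::fabs(g + thr);
      else w = std::max(0.0, std::fabs(g) - thr);
      if (w > viol) viol = w;
    }
    kkt[l] = viol;
    int na = 0;
    for (int j = 0; j < P; ++j) {
      beta(j, l) = b[j];
      if (b[j] != 0.0) ++na;
    }
    nact[l] = na;
    if (max_active >= 0 && na > max_active) {
      for (int l2 = l + 1; l2 < L; ++l2) {
        truncated[l2] = true;
        nact[l2] = na;
        for (int j = 0; j < P; ++j) beta(j, l2) = b[j];
      }
      break;
    }
  }
  return List::create(_["beta"] = beta, _["kkt"] = kkt,
                      _["n_active"] = nact, _["truncated"] = truncated);
}

// Stability-selection accumulator for one subsample of a node network.
//
// G is the Gram matrix of ALL standardized nodes on the subsample.  For
// each response r the design is every other node: feature r is excluded
// via an infinite penalty instead of forming the submatrix, and the
// correlation vector is column r of G.  Selection indicators at each
// penalty are accumulated into `counts`, a p*p*L integer array laid out
// as counts[feature + p*(response + p*lambda_index)] with the lambda
// index following the DECREASING lambda order given here.
//
// wts holds the randomized-lasso weights (penalty factor = 1/weight),
// one column per response; non-finite entries exclude a feature.
// max_active truncates the saturated end of each path as in
// lasso_path_gram (counts there keep the last computed solution).
// [[Rcpp::export]]
void stability_accumulate(const NumericMatrix& G, double n,
                          const NumericVector& lambdas_desc,
                          const NumericMatrix& wts, double tol,
                          int max_iter, int max_active,
                          IntegerVector counts) {
  const int p = G.ncol();
  const int L = lambdas_desc.size();
  std::vector<double> b(p), v(p), pf(p);
  std::vector<int> active;
  for (int r = 0; r < p; ++r) {
    for (int j = 0; j < p; ++j) {
      b[j] = 0.0; v[j] = 0.0;
      const double w = wts(j, r);
      pf[j] = (j == r || !std::isfinite(w) || w <= 0) ?
        R_PosInf : 1.0 / w;
    }
    const double* c = &G(0, r);
    // no coefficient can enter above lam_entry = max_j |c_j|/(n pf_j);
    // those grid points keep the zero solution without a sweep
    double lam_entry = 0.0;
    for (int j = 0; j < p; ++j)
      if (std::isfinite(pf[j])) {
        const double e = std::fabs(c[j]) / (n * pf[j]);
        if (e > lam_entry) lam_entry = e;
      }
    for (int l = 0; l < L; ++l) {
      if (lambdas_desc[l] >= lam_entry) continue;
      cd_solve(c, &G(0, 0), p, n, lambdas_desc[l], pf.data(), tol,
               max_iter, b.data(), v.data(), active);
      int na = 0;
      int* cl = &counts[p * (r + p * l)];
      for (int j = 0; j < p; ++j)
        if (b[j] != 0.0) { ++cl[j]; ++na; }
      if (max_active >= 0 && na > max_active) {
        for (int l2 = l + 1; l2 < L; ++l2) {
          int* cl2 = &counts[p * (r + p * l2)];
          for (int j = 0; j < p; ++j) if (b[j] != 0.0) ++cl2[j];
        }
        break;
      }
    }
  }
}
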