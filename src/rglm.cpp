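#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Bagged forward-selection GLM ensemble.
//
// For each bag: bootstrap the samples, draw a random candidate subset of
// columns, then run greedy forward selection by AIC (Gaussian likelihood,
// AIC = n log(RSS/n) + 2k). Selection uses an implicit Gram-Schmidt
// factorization: candidate columns stay fixed while their projections onto
// the orthonormal basis of accepted columns are tracked incrementally, so
// each step costs one pass over the candidate block. Returns, per column
// of X, the number of bags whose final model contains that column.
// Deterministic for a fixed seed (own modulo sampling on a mt19937 stream,
// independent of platform distribution implementations).
//
// [[Rcpp::export]]
IntegerVector rglm_bag_counts(NumericMatrix X, NumericVector y,
                              int n_bags, int n_candidates, int max_terms,
                              int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n_candidates < 1) n_candidates = 1;
  if (n_candidates > p) n_candidates = p;
  const int nc = n_candidates;
  IntegerVector counts(p);
  std::mt19937 rng(static_cast<uint32_t>(seed));

  std::vector<int> idx(n), cand(p), sel(max_terms);
  std::vector<double> yb(n), zres(n);
  std::vector<double> Z(static_cast<size_t>(nc) * n);  // candidate j at Z[j*n ..]
  std::vector<double> Q(static_cast<size_t>(max_terms) * n), Qy(max_terms);
  std::vector<double> P(static_cast<size_t>(nc) * max_terms);
  std::vector<double> res_ss(nc), res_xy(nc);
  std::vector<bool> used(nc);

  for (int b = 0; b < n_bags; ++b) {
    for (int i = 0; i < n; ++i) idx[i] = rng() % n;
    for (int j = 0; j < p; ++j) cand[j] = j;
    for (int j = 0; j < nc; ++j) {
      int k = j + (rng() % (p - j));
      std::swap(cand[j], cand[k]);
    }
    double ym = 0.0;
    for (int i = 0; i < n; ++i) ym += y[idx[i]];
    ym /= n;
    double rss = 0.0;
    for (int i = 0; i < n; ++i) { yb[i] = y[idx[i]] - ym; rss += yb[i] * yb[i]; }
    if (rss <= 0.0) continue;
    for (int j = 0; j < nc; ++j) {
      double* zj = &Z[static_cast<size_t>(j) * n];
      const int c = cand[j];
      double m = 0.0;
      for (int i = 0; i < n; ++i) { zj[i] = X(idx[i], c); m += zj[i]; }
      m /= n;
      double ss = 0.0, xy = 0.0;
      for (int i = 0; i < n; ++i) {
        zj[i] -= m;
        ss += zj[i] * zj[i];
        xy += zj[i] * yb[i];
      }
      res_ss[j] = ss;
      res_xy[j] = xy;
      used[j] = false;
    }
    int k_sel = 0;
    double aic = n * std::log(rss / n) + 2.0;
    for (int step = 0; step < max_terms; ++step) {
      int best = -1;
      double best_gain = 0.0;
      for (int j = 0; j < nc; ++j) {
        if (used[j] || res_ss[j] < 1e-10 * n) continue;
        double gain = res_xy[j] * res_xy[j] / res_ss[j];
        if (gain > best_gain) { best_gain = gain; best = j; }
      }
      if (best < 0) break;
      double rss_new = rss - best_gain;
      if (rss_new < 1e-12) rss_new = 1e-12;
      double aic_new = n * std::log(rss_new / n) + 2.0 * (step + 2.0);
      if (aic_new >= aic) break;
      // residualize the accepted column against the current basis
      const double* zb = &Z[static_cast<size_t>(best) * n];
      for (int i = 0; i < n; ++i) zres[i] = zb[i];
      for (int k = 0; k < k_sel; ++k) {
        const double pk = P[static_cast<size_t>(best) * max_terms + k];
        const double* qk = &Q[static_cast<size_t>(k) * n];
        for (int i = 0; i < n; ++i) zres[i] -= pk * qk[i];
      }
      double nrm = 0.0;
      for (int i = 0; i < n; ++i) nrm += zres[i] * zres[i];
      nrm = std::sqrt(nrm);
      if (nrm < 1e-10) { used[best] = true; continue; }
      double* qn = &Q[static_cast<size_t>(k_sel) * n];
      for (int i = 0; i < n; ++i) qn[i] = zres[i] / nrm;
      double qy = 0.0;
      for (int i = 0; i < n; ++i) qy += qn[i] * yb[i];
      Qy[k_sel] = qy;
      // one pass: project every candidate on the new basis vector
      for (int j = 0; j < nc; ++j) {
        if (used[j]) continue;
        const double* zj = &Z[static_cast<size_t>(j) * n];
        double qz = 0.0;
        for (int i = 0; i < n; ++i) qz += qn[i] * zj[i];
        P[static_cast<size_t>(j) * max_terms + k_sel] = qz;
        res_ss[j] -= qz * qz;
        res_xy[j] -= qz * qy;
      }
      used[best] = true;
      sel[k_sel] = cand[best];
      ++k_sel;
      rss = rss_new;
      aic = aic_new;
    }
    for (int s = 0; s < k_sel; ++s) counts[sel[s]] += 1;
  }
  return counts;
}
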