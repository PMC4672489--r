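#include <Rcpp.h>
using namespace Rcpp;

// Single-pass (Welford) moment accumulation of a batch of points grouped by
// aggregation window. Points are processed in arrival order; `g` maps each
// point to a 1-based group index (one group per window), `ngroups` is the
// number of distinct windows in the batch.
//
// Per group the accumulator tracks: count, running mean, m2 (sum of squared
// deviations), min/max with earliest occurrence time on ties, and the point
// with the greatest data timestamp (last). Non-finite values must be
// filtered out by the caller.
// [[Rcpp::export(name = ".groupWelford")]]
List groupWelford(IntegerVector g, NumericVector t, NumericVector v,
                  int ngroups) {
  const R_xlen_t n = g.size();
  if (t.size() != n || v.size() != n)
    stop("t, v and g must have equal length");

  IntegerVector count(ngroups, 0);
  NumericVector mean(ngroups, 0.0), m2(ngroups, 0.0);
  NumericVector mn(ngroups), mn_t(ngroups), mx(ngroups), mx_t(ngroups);
  NumericVector last_v(ngroups), last_t(ngroups);

  for (R_xlen_t i = 0; i < n; ++i) {
    const int k = g[i] - 1;
    if (k < 0 || k >= ngroups) stop("group index out of range");
    const double ti = t[i], vi = v[i];
    if (count[k] == 0) {
      count[k] = 1;
      mean[k] = vi;
      m2[k] = 0.0;
      mn[k] = vi; mn_t[k] = ti;
      mx[k] = vi; mx_t[k] = ti;
      last_v[k] = vi; last_t[k] = ti;
    } else {
      const int c = ++count[k];
      const double delta = vi - mean[k];
      mean[k] += delta / c;
      m2[k] += delta * (vi - mean[k]);
      if (vi < mn[k] || (vi == mn[k] && ti < mn_t[k])) { mn[k] = vi; mn_t[k] = ti; }
      if (vi > mx[k] || (vi == mx[k] && ti < mx_t[k])) { mx[k] = vi; mx_t[k] = ti; }
      if (ti > last_t[k]) { last_v[k] = vi; last_t[k] = ti; }
    }
  }

  return List::create(
      _["count"] = count, _["mean"] = mean, _["m2"] = m2,
      _["min"] = mn, _["min_time"] = mn_t,
      _["max"] = mx, _["max_time"] = mx_t,
      _["last"] = last_v, _["last_time"] = last_t);
}
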