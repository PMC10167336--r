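#include <Rcpp.h>
using namespace Rcpp;

// REML (independent-contrasts) log-likelihood of Brownian motion on a
// rooted tree. Edges must be in postorder; nodes 0-based with tips
// 0..ntip-1 matching the rows of Y. `rates` gives one variance scalar per
// trait column; `el` are the (possibly rescaled) branch lengths.
// [[Rcpp::export]]
double bm_reml_loglik_cpp(IntegerVector parent, IntegerVector child,
                          NumericVector el, int ntip,
                          NumericMatrix Y, NumericVector rates) {
  const int ne = parent.size();
  const int k = Y.ncol();
  const int ntot = ntip + ne; // upper bound on node count
  std::vector<double> vlen(ntot, 0.0);
  std::vector<bool> has(ntot, false);
  std::vector<std::vector<double> > val(ntot);
  const double LOG2PI = 1.8378770664093454836;
  double ll = 0.0;
  for (int e = 0; e < ne; e++) {
    int pa = parent[e], ch = child[e];
    double vch;
    std::vector<double> xch(k);
    if (ch < ntip) {
      vch = 0.0;
      for (int t = 0; t < k; t++) xch[t] = Y(ch, t);
    } else {
      vch = vlen[ch];
      xch = val[ch];
    }
    double w = el[e] + vch;
    if (!has[pa]) {
      val[pa] = xch;
      vlen[pa] = w;
      has[pa] = true;
    } else {
      double vp = vlen[pa];
      double vsum = vp + w;
      if (vsum < 1e-300) vsum = 1e-300;
      for (int t = 0; t < k; t++) {
        double u = val[pa][t] - xch[t];
        double vv = vsum * rates[t];
        if (vv < 1e-300) vv = 1e-300;
        ll += -0.5 * (LOG2PI + std::log(vv) + u * u / vv);
      }
      double denom = vsum;
      for (int t = 0; t < k; t++)
        val[pa][t] = (val[pa][t] * w + xch[t] * vp) / denom;
      vlen[pa] = (vp * w) / denom;
    }
  }
  return ll;
}
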