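#include <Rcpp.h>
using namespace Rcpp;

// Gaussian product-kernel density of `data` (one kernel per row, per-axis
// bandwidths) evaluated at the rows of `query`. Densities are averaged over
// kernels, so the result integrates to 1 over R^d.
// [[Rcpp::export]]
NumericVector kde_gauss_eval(NumericMatrix query, NumericMatrix data,
                             NumericVector bandwidth) {
  const int nq = query.nrow(), nd = data.nrow(), d = query.ncol();
  if (data.ncol() != d)
    stop("query and data dimension mismatch");
  if (bandwidth.size() != d)
    stop("need one bandwidth per axis");
  double lognorm = -0.5 * d * std::log(2.0 * M_PI) - std::log((double)nd);
  for (int j = 0; j < d; ++j) {
    if (bandwidth[j] <= 0.0) stop("bandwidths must be positive");
    lognorm -= std::log(bandwidth[j]);
  }
  const double norm = std::exp(lognorm);
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double s = 0.0;
    for (int i = 0; i < nd; ++i) {
      double e = 0.0;
      for (int j = 0; j < d; ++j) {
        const double z = (query(q, j) - data(i, j)) / bandwidth[j];
        e += z * z;
      }
      s += std::exp(-0.5 * e);
    }
    out[q] = s * norm;
  }
  return out;
}
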