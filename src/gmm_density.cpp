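#include <Rcpp.h>
using namespace Rcpp;

// Per-localization Gaussian-mixture density of a discretized model.
//
// Each model point v_j (weight q_j) contributes an axis-aligned Gaussian with
// per-localization covariance diag(sigma^2 + eps^2).  Densities are returned
// per localization, normalized by sum(q) and (2*pi)^(D/2) * prod(sd).
//
// x, s: K x D coordinates and precisions; v: J x D model points; q: length J.
// [[Rcpp::export(name = ".gmmDensity")]]
NumericVector gmmDensity(NumericMatrix x, NumericMatrix s,
                         NumericMatrix v, NumericVector q,
                         double eps) {
  const int K = x.nrow(), D = x.ncol(), J = v.nrow();
  if (s.nrow() != K || s.ncol() != D)
    stop("coords and precisions must have identical dimensions");
  if (q.size() != J)
    stop("weights must match model points");
  NumericVector out(K);
  double qsum = 0.0;
  for (int j = 0; j < J; ++j) qsum += q[j];
  if (qsum <= 0.0) stop("model weights must sum to a positive value");
  const double e2 = eps * eps;
  const double log2pi = std::log(2.0 * M_PI);
  for (int k = 0; k < K; ++k) {
    // per-localization variances and normalizing constant
    double var[3], lognorm = -0.5 * D * log2pi;
    for (int d = 0; d < D; ++d) {
      var[d] = s(k, d) * s(k, d) + e2;
      lognorm -= 0.5 * std::log(var[d]);
    }
    const double norm = std::exp(lognorm);
    double acc = 0.0;
    for (int j = 0; j < J; ++j) {
      double m = 0.0;
      for (int d = 0; d < D; ++d) {
        const double dx = x(k, d) - v(j, d);
        m += dx * dx / var[d];
      }
      // contributions below exp(-40) ~ 4e-18 of the peak are negligible
      if (m < 80.0) acc += q[j] * std::exp(-0.5 * m);
    }
    out[k] = norm * acc / qsum;
  }
  return out;
}
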