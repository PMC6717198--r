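#include <Rcpp.h>
using namespace Rcpp;

// Log-likelihood of placing one node at each candidate angle, against a set
// of already-placed nodes. Edge terms use log p(x), non-edge terms
// log(1 - p(x)), with the Fermi-Dirac p at disk radius R, temperature T.
// This is the hot loop of the embedding: O(grid * placed) per node.
// [[Rcpp::export]]
NumericVector ll_candidate_angles(NumericVector grid, double r_i,
                                  NumericVector r_j, NumericVector theta_j,
                                  IntegerVector adj, double R, double T) {
  const int G = grid.size(), n = r_j.size();
  NumericVector ll(G);
  const double si = std::sinh(r_i);
  std::vector<double> cdr(n), sj(n);
  for (int j = 0; j < n; ++j) {
    cdr[j] = std::cosh(r_i - r_j[j]);
    sj[j] = std::sinh(r_j[j]);
  }
  const double twoT = 2.0 * T;
  for (int g = 0; g < G; ++g) {
    double acc = 0.0;
    const double th = grid[g];
    for (int j = 0; j < n; ++j) {
      double d = std::fabs(th - theta_j[j]);
      double dth = M_PI - std::fabs(M_PI - d);  // shorter arc
      // cancellation-free form: cosh(dr) + sinh r_i sinh r_j 2 sin^2(dth/2)
      double hs = std::sin(0.5 * dth);
      double arg = cdr[j] + si * sj[j] * 2.0 * hs * hs;
      if (arg < 1.0) arg = 1.0;
      double x = std::acosh(arg);
      double z = (x - R) / twoT;
      double logp = (z > 0) ? -z - std::log1p(std::exp(-z))
                            : -std::log1p(std::exp(z));
      acc += adj[j] ? logp : (logp + z);  // log(1-p) = log p + z
    }
    ll[g] = acc;
  }
  return ll;
}
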