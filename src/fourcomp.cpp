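// Compiled cost kernel for the four-compartment benchmark: builds the 4x4
// rate matrix from the 16-parameter vector (rho_A..rho_D, then mu_XY in
// row-major pair order AB, AC, AD, BA, ...), propagates the linear system on
// the observation grid and accumulates the weighted squared residuals.
// Called ~10^3 times per model fit and ~10^5 times per model-space search.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".fc_cost_cpp")]]
double fc_cost_cpp(const arma::vec& par, const arma::vec& times,
                   const arma::mat& y, const arma::mat& w,
                   const arma::vec& x0) {
  arma::mat M(4, 4, arma::fill::zeros);
  int k = 4;
  for (int from = 0; from < 4; ++from) {
    double out = 0.0;
    for (int to = 0; to < 4; ++to) {
      if (to == from) continue;
      const double mu = par[k++];
      M(to, from) += mu;
      out += mu;
    }
    M(from, from) = par[from] - out;
  }
  const arma::uword nt = times.n_elem;
  std::vector<double> dts;
  std::vector<arma::mat> props;
  arma::vec x = x0;
  double tprev = 0.0, cost = 0.0;
  for (arma::uword i = 0; i < nt; ++i) {
    const double dt = times[i] - tprev;
    tprev = times[i];
    if (dt > 0) {
      int found = -1;
      for (size_t j = 0; j < dts.size(); ++j) {
        if (dts[j] == dt) { found = static_cast<int>(j); break; }
      }
      if (found < 0) {
        props.push_back(arma::expmat(M * dt));
        dts.push_back(dt);
        found = static_cast<int>(dts.size()) - 1;
      }
      x = props[found] * x;
    }
    for (int c = 0; c < 4; ++c) {
      const double r = (y(i, c) - x[c]) / w(i, c);
      cost += r * r;
    }
  }
  return cost;
}
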