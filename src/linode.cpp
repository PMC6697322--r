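// Fast propagation of linear ODE systems dx/dt = M x on a time grid.
// The propagator over a grid step of width dt is expm(M * dt); repeated step
// widths reuse one propagator, so equidistant grids cost a single matrix
// exponential. Used by the benchmark cost functions, which evaluate such
// trajectories hundreds of thousands of times during a model-space search.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".lin_traj_cpp")]]
arma::mat lin_traj_cpp(const arma::mat& M, const arma::vec& x0,
                       const arma::vec& times) {
  const arma::uword nt = times.n_elem;
  const arma::uword n = x0.n_elem;
  arma::mat out(nt, n);
  arma::vec x = x0;
  double tprev = 0.0;
  std::vector<double> dts;
  std::vector<arma::mat> props;
  for (arma::uword i = 0; i < nt; ++i) {
    const double dt = times[i] - tprev;
    if (dt < 0) Rcpp::stop("'times' must be non-decreasing");
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
    out.row(i) = x.t();
  }
  return out;
}
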