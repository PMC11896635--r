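#include <RcppArmadillo.h>
#include "substep_taylor.h"
// [[Rcpp::depends(RcppArmadillo)]]

// Substepped unitary electronic propagation with linear interpolation of
// energies and time-derivative couplings between two nuclear steps.
//
// Per substep the coefficient vector is advanced by the exact exponential of
// the anti-Hermitian generator -(i diag(E) + T) h, evaluated at the substep
// midpoint, via the eigendecomposition of the Hermitian matrix
// M = diag(E) - i T (T real antisymmetric), so the propagation is unitary to
// machine precision. When `active` >= 1 (1-based) the fewest-switches
// outflow g_j = sum_substeps max(0, 2 Re(T_aj c_j* c_a) h / |c_a|^2) is
// accumulated with the coefficients at each substep start.
//
// Units: energies in hartree, T in 1/atomic-time, dt in atomic time units.
// [[Rcpp::export(name = ".propagate_substeps")]]
Rcpp::List propagate_substeps(const arma::cx_vec& c0,
                              const arma::vec& E_prev, const arma::vec& E_curr,
                              const arma::mat& T_prev, const arma::mat& T_curr,
                              double dt, int n_sub, int active) {
  arma::cx_vec c = c0;
  const arma::uword d = c.n_elem;
  arma::vec g(d, arma::fill::zeros);
  const double h = dt / n_sub;
  for (int s = 0; s < n_sub; ++s) {
    const double fm = (s + 0.5) / n_sub;
    const arma::vec E = (1.0 - fm) * E_prev + fm * E_curr;
    const arma::mat T = (1.0 - fm) * T_prev + fm * T_curr;
    if (active >= 1) {
      const arma::uword a = active - 1;
      const std::complex<double> ca = c(a);
      const double pa = std::norm(ca);
      if (pa > 1e-12) {
        for (arma::uword j = 0; j < d; ++j) {
          if (j == a) continue;
          const double flux =
            2.0 * std::real(std::conj(c(j)) * ca * T(a, j)) * h / pa;
          if (flux > 0.0) g(j) += flux;
        }
      }
    }
    substep_apply(c, E, T, h);
  }
  return Rcpp::List::create(Rcpp::Named("c") = c, Rcpp::Named("g") = g);
}
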