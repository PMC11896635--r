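#pragma once
#include <RcppArmadillo.h>

// Apply the exact substep propagator exp(-(i diag(E) + T) h) to c, where E
// is real and T is real antisymmetric (the generator is anti-Hermitian, so
// the map is unitary). The mean energy is factored out as a global phase
// and the remainder applied as a Taylor series on the vector; with
// ||h (E - Ebar)|| and ||h T|| well below 1 this converges to machine
// precision in a handful of matrix-vector products.
inline void substep_apply(arma::cx_vec& c, const arma::vec& E,
                          const arma::mat& T, double h) {
  const double ebar = arma::mean(E);
  const arma::vec Es = E - ebar;
  arma::cx_vec term = c;
  arma::cx_vec acc = c;
  for (int n = 1; n <= 40; ++n) {
    term = (arma::cx_double(0.0, -h) / double(n)) * (Es % term) -
           (h / double(n)) * (T * term);
    acc += term;
    if (arma::norm(term, 2) < 1e-16) break;
  }
  c = std::exp(arma::cx_double(0.0, -ebar * h)) * acc;
}
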