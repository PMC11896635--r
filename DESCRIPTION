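Package: spinhop
Title: Spin-Adiabatic Surface Hopping with Accelerated Intersystem Crossing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed quantum-classical simulation of intersystem crossing in
    organic chromophores on model vibronic Hamiltonians. Implements
    fewest-switches surface hopping in the spin-adiabatic basis of a complex
    Hermitian singlet-triplet Hamiltonian, Wigner sampling of canonical
    harmonic initial conditions, spin-orbit-coupling scaling with lifetime
    extrapolation back to the unscaled coupling, nuclear-ensemble absorption
    spectra, triplet quantum yield and Einstein emission-rate kinetics,
    non-parallelity curve metrics, hop-character analysis and qualitative
    one-center spin-orbit selection rules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
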