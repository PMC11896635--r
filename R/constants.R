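#' Physical constants (CODATA 2018) and unit conversions
#'
#' Single source of truth for every module: SI fundamental constants and the
#' conversion factors between the package's internal atomic units and the
#' interface units (eV, cm^-1, fs, amu, kelvin).
#'
#' Internally all dynamics is carried out in Hartree atomic units
#' (hbar = m_e = e = 1); coordinates and momenta are in atomic units,
#' energies in hartree, time in atomic time units.
#'
#' @return A named list of constants. SI members: `e` (C), `m_e` (kg),
#'   `h` (J s), `hbar` (J s), `eps0` (F/m), `c` (m/s), `k_B` (J/K).
#'   Conversions: `hartree_eV`, `cm1_hartree`, `fs_au` (atomic time units per
#'   fs), `amu_me` (electron masses per amu), `kB_hartree_K`.
#' @examples
#' physical_constants()$hartree_eV
#' @export
physical_constants <- function() {
  list(
    e    = 1.602176634e-19,
    m_e  = 9.1093837015e-31,
    h    = 6.62607015e-34,
    hbar = 1.054571817e-34,
    eps0 = 8.8541878128e-12,
    c    = 2.99792458e8,
    k_B  = 1.380649e-23,
    hartree_eV   = 27.211386245988,
    cm1_hartree  = 4.556335252912e-6,
    fs_au        = 41.341373335183,
    amu_me       = 1822.888486209,
    kB_hartree_K = 3.166811563e-6
  )
}

## internal shorthands, fixed at build time
.const <- list(
  hartree_eV   = 27.211386245988,
  cm1_hartree  = 4.556335252912e-6,
  fs_au        = 41.341373335183,
  amu_me       = 1822.888486209,
  kB_hartree_K = 3.166811563e-6
)

ev_to_au  <- function(x) x / .const$hartree_eV
au_to_ev  <- function(x) x * .const$hartree_eV
cm1_to_au <- function(x) x * .const$cm1_hartree
au_to_cm1 <- function(x) x / .const$cm1_hartree
fs_to_au  <- function(x) x * .const$fs_au
au_to_fs  <- function(x) x / .const$fs_au
amu_to_au <- function(x) x * .const$amu_me
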