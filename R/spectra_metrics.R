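#' Nuclear-ensemble absorption spectrum
#'
#' Builds a photoabsorption cross-section on an energy grid from an ensemble
#' of per-configuration vertical excitations: each transition contributes a
#' unit-area Gaussian line shape centred at its excitation energy, weighted
#' by its oscillator strength; configurations are AVERAGED (not summed), so
#' the spectrum converges with ensemble size. Cross-sections are reported in
#' arbitrary units (up to the energy-dependent physical prefactor), which is
#' sufficient for band positions and shifts. No vibrational fine structure
#' is produced — that is inherent to the nuclear-ensemble approach.
#'
#' @param excitations Tibble with columns `config` (configuration id),
#'   `energy_eV` (vertical excitation energy) and `strength` (oscillator
#'   strength). A configuration with no rows contributes zero; include its
#'   id in `configs` to count it in the average.
#' @param width_eV Gaussian line width (standard deviation), eV, > 0.
#'   Default 0.05.
#' @param grid Optional energy grid (eV, strictly increasing); default: 400
#'   points spanning the excitation range padded by 5 widths.
#' @param configs Optional vector of configuration ids defining the ensemble
#'   (defaults to the ids present in `excitations`).
#' @return Tibble of class `nea_spectrum` with `energy_eV`, `cross_section`;
#'   attributes `width_eV`, `n_configs`, `n_states`.
#' @export
nea_spectrum <- function(excitations, width_eV = 0.05, grid = NULL,
                         configs = NULL) {
  if (width_eV <= 0) stop("width_eV must be > 0")
  excitations <- tibble::as_tibble(excitations)
  if (is.null(configs)) configs <- unique(excitations$config)
  n_cfg <- length(configs)
  if (n_cfg == 0L) stop("empty configuration list")
  if (is.null(grid)) {
    if (nrow(excitations) == 0L) stop("cannot infer a grid from zero transitions")
    rng <- range(excitations$energy_eV)
    grid <- seq(rng[1] - 5 * width_eV, rng[2] + 5 * width_eV, length.out = 400L)
  }
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  sigma <- numeric(length(grid))
  for (r in seq_len(nrow(excitations)))
    sigma <- sigma + excitations$strength[r] *
      stats::dnorm(grid, excitations$energy_eV[r], width_eV)
  out <- tibble::tibble(energy_eV = grid, cross_section = sigma / n_cfg)
  structure(out, width_eV = width_eV, n_configs = n_cfg,
            n_states = nrow(excitations),
            class = c("nea_spectrum", class(out)))
}

#' Non-parallelity between two potential energy curves
#'
#' \deqn{NP(f, g) = \max_R |f(R) - g(R)| \;-\; \min_R |f(R) - g(R)|}
#' evaluated pointwise on a shared grid (no interpolation). Zero when the
#' curves differ by a constant shift; symmetric in its arguments; invariant
#' under adding the same curve to both.
#'
#' @param f_values,g_values Numeric energy vectors (eV) on the same grid,
#'   equal length >= 2.
#' @return Non-parallelity in eV (>= 0).
#' @examples
#' non_parallelity(c(0, 1, 2), c(0.3, 1.3, 2.3))  # constant shift: 0
#' @export
non_parallelity <- function(f_values, g_values) {
  if (length(f_values) != length(g_values)) stop("curve length mismatch")
  if (length(f_values) < 2L) stop("curves need at least 2 points")
  d <- abs(f_values - g_values)
  max(d) - min(d)
}
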