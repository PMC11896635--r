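#' Assemble the two-component spin Hamiltonian
#'
#' Builds the complex Hermitian matrix H in the spin-diabatic basis: real
#' scalar energies on the diagonal, spin-orbit coupling in the
#' singlet-triplet off-diagonal blocks scaled by the acceleration factor
#' alpha. Scaling touches only the SOC entries — the diagonal (and any
#' same-spin couplings, which in this package live in the scalar layer) is
#' left unchanged, mirroring coupling-scaled accelerated dynamics where NACs
#' are not scaled.
#'
#' @param scalar_energies Real vector of spin-diabatic energies (triplet
#'   components repeated), hartree or any consistent unit.
#' @param soc_blocks Complex `d x d` matrix of SOC couplings (same unit),
#'   Hermitian, zero diagonal.
#' @param alpha SOC scaling factor, >= 0.
#' @return Complex Hermitian matrix of class `spin_hamiltonian` with
#'   attribute `alpha`.
#' @export
assemble_spin_hamiltonian <- function(scalar_energies, soc_blocks, alpha = 1) {
  d <- length(scalar_energies)
  soc_blocks <- as.matrix(soc_blocks)
  if (!all(dim(soc_blocks) == c(d, d))) stop("soc_blocks must be d x d")
  if (alpha < 0) stop("alpha must be >= 0")
  herm_err <- max(Mod(soc_blocks - Conj(t(soc_blocks))))
  scale_ref <- max(Mod(soc_blocks), 1e-300)
  if (herm_err > 1e-10 * max(scale_ref, 1))
    stop("soc_blocks is not Hermitian (max deviation ", signif(herm_err, 3), ")")
  H <- diag(as.numeric(scalar_energies), nrow = d) + alpha * soc_blocks
  structure(H, alpha = alpha, class = c("spin_hamiltonian", class(H)))
}

#' Diagonalize a spin Hamiltonian into quasirelativistic states
#'
#' Solves H U = U E for a complex Hermitian H. Columns of U are the
#' spin-adiabatic states expressed in the spin-diabatic basis; eigenvalues
#' are returned ascending. Unitarity and the reconstruction residual
#' ||H U - U E|| are the invariants asserted in the test suite.
#'
#' @param H Complex Hermitian matrix (e.g. from
#'   [assemble_spin_hamiltonian()]).
#' @return A list of class `quasirel_states` with `energies` (ascending) and
#'   `vectors` (unitary matrix U).
#' @export
diagonalize_spin_hamiltonian <- function(H) {
  if (any(!is.finite(Re(H))) || any(!is.finite(Im(H)))) stop("non-finite entries in H")
  e <- eigen(H, symmetric = TRUE)
  idx <- order(e$values)
  structure(list(energies = e$values[idx],
                 vectors = matrix(as.complex(e$vectors[, idx]), nrow = nrow(H))),
            class = "quasirel_states")
}

#' Gauge-align eigenvectors between consecutive time steps
#'
#' Removes the arbitrary per-column phase and ordering of an
#' eigendecomposition by matching columns of `U_curr` to `U_prev` via maximal
#' absolute overlap and rotating each matched column's phase so its overlap
#' with the previous column is real and non-negative. Columns inside
#' near-degenerate clusters (consecutive energy gap below `degeneracy_tol`)
#' are aligned jointly by the polar factor of the overlap block, avoiding
#' arbitrary mixing within the subspace.
#'
#' @param U_prev,U_curr Unitary matrices of equal dimension.
#' @param metric Optional overlap metric between the two steps' basis sets
#'   (defaults to the identity); overlaps are `Conj(t(U_prev)) %*% metric
#'   %*% U_curr`.
#' @param energies Optional eigenvalue vector of the current step, used to
#'   detect degenerate clusters and returned permuted alongside.
#' @param degeneracy_tol Energy gap (same unit as `energies`) below which
#'   columns are treated as a degenerate cluster. Default 1e-10.
#' @return The adjusted unitary, with attributes `permutation` (the column
#'   of `U_curr` each output column came from) and, if supplied, `energies`.
#' @export
align_gauge <- function(U_prev, U_curr, metric = NULL, energies = NULL,
                        degeneracy_tol = 1e-10) {
  d <- ncol(U_prev)
  if (!all(dim(U_curr) == dim(U_prev))) stop("dimension mismatch")
  O <- if (is.null(metric)) Conj(t(U_prev)) %*% U_curr
       else Conj(t(U_prev)) %*% metric %*% U_curr
  ## greedy max-|overlap| assignment (adequate away from pathological mixing)
  perm <- integer(d)
  absO <- Mod(O)
  taken_row <- rep(FALSE, d); taken_col <- rep(FALSE, d)
  for (step in seq_len(d)) {
    m <- absO
    m[taken_row, ] <- -1; m[, taken_col] <- -1
    ij <- arrayInd(which.max(m), dim(m))
    second <- sort(m[ij[1], m[ij[1], ] >= 0], decreasing = TRUE)
    if (length(second) > 1 && abs(second[1] - second[2]) < 1e-12)
      message("align_gauge: ambiguous column assignment resolved by index order")
    perm[ij[1]] <- ij[2]
    taken_row[ij[1]] <- TRUE; taken_col[ij[2]] <- TRUE
  }
  U <- U_curr[, perm, drop = FALSE]
  Operm <- O[, perm, drop = FALSE]
  e_out <- if (!is.null(energies)) energies[perm] else NULL

  ## degenerate clusters (on permuted energies): joint polar alignment
  clusters <- list()
  if (!is.null(e_out) && d > 1L) {
    grp <- cumsum(c(1, diff(e_out) > degeneracy_tol))
    clusters <- split(seq_len(d), grp)
    clusters <- clusters[vapply(clusters, length, 1L) > 1L]
  }
  in_cluster <- rep(FALSE, d)
  for (cl in clusters) {
    in_cluster[cl] <- TRUE
    B <- Operm[cl, cl, drop = FALSE]
    sv <- svd(B)
    W <- sv$u %*% Conj(t(sv$v))          # polar factor of the overlap block
    U[, cl] <- U[, cl] %*% Conj(t(W))
  }
  for (j in which(!in_cluster)) {
    o <- Operm[j, j]
    if (Mod(o) > 1e-14) U[, j] <- U[, j] * Conj(o) / Mod(o)
  }
  attr(U, "permutation") <- perm
  if (!is.null(e_out)) attr(U, "energies") <- e_out
  U
}

#' Back-transform spin-adiabatic coefficients to the spin-diabatic basis
#'
#' Computes b = U c, the expansion of the electronic wave function in the
#' spin-diabatic basis. The transformation is unitary, so the norm of `c` is
#' preserved exactly (up to floating-point roundoff) and |b_i|^2 are the
#' spin-diabatic state populations.
#'
#' @param U Unitary matrix (columns: spin-adiabatic states).
#' @param c_coef Complex coefficient vector in the spin-adiabatic basis,
#'   normalized to 1 within 1e-8.
#' @return Complex vector b of spin-diabatic amplitudes.
#' @export
back_transform <- function(U, c_coef) {
  if (length(c_coef) != ncol(U)) stop("dimension mismatch between U and c")
  nrm <- sqrt(sum(Mod(c_coef)^2))
  if (abs(nrm - 1) > 1e-8) stop("coefficient vector is not normalized (norm ", nrm, ")")
  as.vector(U %*% c_coef)
}

#' Ensemble-averaged spin-diabatic populations
#'
#' Averages the per-trajectory spin-diabatic populations |b_i(t)|^2 over an
#' ensemble, summing the three components of each triplet into their parent
#' triplet. Trajectories are truncated to the common time range. Populations
#' sum to 1 at every time point.
#'
#' @param trajectories List of `trajectory` objects sharing a time step.
#' @return A tibble of class `population_series` in long format: `t_fs`,
#'   `state` (factor, S0...T_nT ordering), `population`; attributes `n_traj`
#'   and `alpha`.
#' @export
ensemble_populations <- function(trajectories) {
  if (length(trajectories) == 0L) stop("empty ensemble")
  n_steps <- min(vapply(trajectories, function(tr) length(tr$times_fs), 1L))
  labels <- trajectories[[1]]$state_labels
  acc <- matrix(0, n_steps, length(labels))
  for (tr in trajectories) acc <- acc + tr$pop_diabatic[seq_len(n_steps), , drop = FALSE]
  acc <- acc / length(trajectories)
  out <- tibble::tibble(
    t_fs = rep(trajectories[[1]]$times_fs[seq_len(n_steps)], times = length(labels)),
    state = factor(rep(labels, each = n_steps), levels = labels),
    population = as.vector(acc)
  )
  structure(out, n_traj = length(trajectories),
            alpha = trajectories[[1]]$params$alpha,
            class = c("population_series", class(out)))
}

#' Sum populations over a set of states
#'
#' Convenience selector on a [ensemble_populations()] series: sums the
#' populations of the named scalar states (or of all singlets / all triplets)
#' per time point.
#'
#' @param series A `population_series` tibble.
#' @param states Character vector of state labels, or `"singlets"` /
#'   `"triplets"` / `"excited_singlets"` shorthands.
#' @return Tibble with `t_fs`, `population`.
#' @export
population_of <- function(series, states) {
  labels <- levels(series$state)
  if (identical(states, "singlets")) states <- grep("^S", labels, value = TRUE)
  else if (identical(states, "triplets")) states <- grep("^T", labels, value = TRUE)
  else if (identical(states, "excited_singlets"))
    states <- setdiff(grep("^S", labels, value = TRUE), "S0")
  if (!all(states %in% labels))
    stop("unknown state label(s): ", paste(setdiff(states, labels), collapse = ", "))
  series |>
    dplyr::filter(.data$state %in% states) |>
    dplyr::group_by(.data$t_fs) |>
    dplyr::summarise(population = sum(.data$population), .groups = "drop")
}
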