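#' Harmonic nuclear mode specification
#'
#' One row per normal mode. Coordinates are one-dimensional atomic-unit
#' coordinates with an explicit reduced mass, so a mode can equally represent
#' a stiff stretch or (with an appropriately scaled mass and unit) a soft
#' out-of-plane bend tracked by a dihedral-like coordinate.
#'
#' @param frequency_cm1 Harmonic frequency, cm^-1, > 0.
#' @param reduced_mass_amu Reduced mass, amu, > 0.
#' @param equilibrium Coordinate origin (atomic units), default 0.
#' @param label Mode label used to reference the mode from coupling tables.
#' @return A tibble with columns `label`, `frequency_cm1`, `reduced_mass_amu`,
#'   `equilibrium`; vector arguments give one row per mode.
#' @export
mode_spec <- function(frequency_cm1, reduced_mass_amu, equilibrium = 0,
                      label = NULL) {
  n <- max(length(frequency_cm1), length(reduced_mass_amu))
  frequency_cm1 <- rep_len(frequency_cm1, n)
  reduced_mass_amu <- rep_len(reduced_mass_amu, n)
  equilibrium <- rep_len(equilibrium, n)
  if (is.null(label)) label <- paste0("q", seq_len(n))
  if (any(!is.finite(frequency_cm1)) || any(frequency_cm1 <= 0))
    stop("mode frequencies must be finite and > 0")
  if (any(!is.finite(reduced_mass_amu)) || any(reduced_mass_amu <= 0))
    stop("mode reduced masses must be finite and > 0")
  if (anyDuplicated(label)) stop("mode labels must be unique")
  tibble::tibble(
    label = as.character(label),
    frequency_cm1 = as.numeric(frequency_cm1),
    reduced_mass_amu = as.numeric(reduced_mass_amu),
    equilibrium = as.numeric(equilibrium)
  )
}

#' Electronic-state specification for a linear vibronic coupling model
#'
#' Defines the spin-free (scalar) electronic structure: vertical energies of
#' singlets (ground state included as S0) and triplets at the coordinate
#' origin, per-state intrastate gradients (kappa), same-spin interstate linear
#' couplings (lambda) and oscillator strengths of the excited singlets.
#'
#' Scalar states are labelled `"S0" ... "S<nS-1>"`, `"T1" ... "T<nT>"`; this
#' ordering (singlets ascending in vertical energy, then triplets ascending)
#' is fixed and asserted by every downstream module.
#'
#' @param n_singlets Number of singlets including the ground state (>= 1).
#' @param n_triplets Number of triplets (>= 0; >= 1 for spin dynamics).
#' @param vertical_energies_eV Numeric, length `n_singlets + n_triplets`,
#'   singlets first: per-state vertical energy at the origin (eV). S0 must be
#'   the singlet minimum; singlet and triplet blocks must each be ascending.
#' @param intrastate_gradients_eV Optional matrix
#'   `(n_singlets + n_triplets) x n_modes` of linear intrastate couplings
#'   kappa (eV per unit coordinate); default all zero.
#' @param interstate_couplings Optional tibble with columns `state_a`,
#'   `state_b` (scalar labels, same spin), `mode` (mode label) and `value_eV`
#'   (linear vibronic coupling lambda, eV per unit coordinate).
#' @param oscillator_strengths Optional numeric, length `n_singlets - 1`,
#'   dimensionless f of S0 -> Sn transitions; default all zero.
#' @return An object of class `electronic_spec`.
#' @export
electronic_spec <- function(n_singlets, n_triplets, vertical_energies_eV,
                            intrastate_gradients_eV = NULL,
                            interstate_couplings = NULL,
                            oscillator_strengths = NULL) {
  n_singlets <- as.integer(n_singlets)
  n_triplets <- as.integer(n_triplets)
  if (n_singlets < 1L) stop("n_singlets must be >= 1 (includes the ground state)")
  if (n_triplets < 0L) stop("n_triplets must be >= 0")
  n_state <- n_singlets + n_triplets
  if (length(vertical_energies_eV) != n_state)
    stop("vertical_energies_eV must have length n_singlets + n_triplets = ", n_state)
  e_s <- vertical_energies_eV[seq_len(n_singlets)]
  if (any(e_s[1] > e_s[-1])) stop("S0 must be the singlet energy minimum at the origin")
  if (is.unsorted(e_s)) stop("singlet vertical energies must be ascending (basis ordering)")
  if (n_triplets > 0L) {
    e_t <- vertical_energies_eV[n_singlets + seq_len(n_triplets)]
    if (is.unsorted(e_t)) stop("triplet vertical energies must be ascending (basis ordering)")
  }
  if (is.null(oscillator_strengths)) oscillator_strengths <- rep(0, max(n_singlets - 1L, 0L))
  if (length(oscillator_strengths) != n_singlets - 1L)
    stop("oscillator_strengths must have length n_singlets - 1")
  if (any(oscillator_strengths < 0)) stop("oscillator strengths must be >= 0")
  structure(
    list(
      n_singlets = n_singlets,
      n_triplets = n_triplets,
      vertical_energies_eV = as.numeric(vertical_energies_eV),
      intrastate_gradients_eV = intrastate_gradients_eV,
      interstate_couplings = interstate_couplings,
      oscillator_strengths = as.numeric(oscillator_strengths)
    ),
    class = "electronic_spec"
  )
}

#' Spin-orbit coupling specification
#'
#' Complex singlet-triplet couplings per (singlet, triplet, M_S component),
#' optionally with a linear/quadratic magnitude modulation along a named
#' coordinate. Triplet components are labelled by M_S in \{-1, 0, +1\}.
#' Modulation adds `linear * d + quadratic * d^2` (d = displacement of the
#' named coordinate from its equilibrium, in that coordinate's own unit) to
#' the coupling magnitude, preserving the complex phase; at the reference
#' geometry the base coupling is returned unchanged.
#'
#' @param couplings Tibble with columns `singlet` (e.g. "S1"), `triplet`
#'   (e.g. "T1"), `component` (-1, 0 or 1), `re_cm1` and optionally `im_cm1`.
#' @param modulation Optional tibble with columns `singlet`, `triplet`,
#'   `component`, `coordinate` (mode label), `linear_cm1`, `quadratic_cm1`.
#' @return An object of class `soc_spec`.
#' @export
soc_spec <- function(couplings, modulation = NULL) {
  req <- c("singlet", "triplet", "component", "re_cm1")
  if (!all(req %in% names(couplings)))
    stop("soc couplings need columns: ", paste(req, collapse = ", "))
  if (!"im_cm1" %in% names(couplings)) couplings$im_cm1 <- 0
  if (!all(couplings$component %in% c(-1L, 0L, 1L)))
    stop("triplet component must be one of -1, 0, 1 (M_S labelling)")
  if (!is.null(modulation)) {
    reqm <- c("singlet", "triplet", "component", "coordinate")
    if (!all(reqm %in% names(modulation)))
      stop("soc modulation needs columns: ", paste(reqm, collapse = ", "))
    if (!"linear_cm1" %in% names(modulation)) modulation$linear_cm1 <- 0
    if (!"quadratic_cm1" %in% names(modulation)) modulation$quadratic_cm1 <- 0
  }
  structure(list(couplings = tibble::as_tibble(couplings),
                 modulation = if (is.null(modulation)) NULL else tibble::as_tibble(modulation)),
            class = "soc_spec")
}

#' Scalar-state labels of a model
#'
#' @param model A `model_system`.
#' @return Character vector `"S0" ... "T<nT>"` in the fixed basis ordering.
#' @export
scalar_labels <- function(model) {
  el <- model$electronic
  c(paste0("S", seq_len(el$n_singlets) - 1L),
    if (el$n_triplets > 0L) paste0("T", seq_len(el$n_triplets)))
}

#' Spin-diabatic basis labels (triplet components expanded)
#'
#' @param model A `model_system`.
#' @return Character vector of length `n_singlets + 3 * n_triplets`; triplets
#'   appear as `"T1(ms=-1)"`, `"T1(ms=0)"`, `"T1(ms=+1)"`, ...
#' @export
spin_basis_labels <- function(model) {
  el <- model$electronic
  tl <- if (el$n_triplets > 0L) {
    as.vector(t(outer(paste0("T", seq_len(el$n_triplets)),
                      c("(ms=-1)", "(ms=0)", "(ms=+1)"), paste0)))
  } else character()
  c(paste0("S", seq_len(el$n_singlets) - 1L), tl)
}

## map a scalar label to its index in S0..S(nS-1), T1..TnT ordering
scalar_index <- function(label, n_singlets, n_triplets) {
  lab <- c(paste0("S", seq_len(n_singlets) - 1L),
           if (n_triplets > 0L) paste0("T", seq_len(n_triplets)))
  idx <- match(label, lab)
  if (anyNA(idx)) stop("unknown state label(s): ",
                       paste(label[is.na(idx)], collapse = ", "))
  idx
}

#' Build a validated linear vibronic coupling model
#'
#' Assembles nuclear modes, scalar electronic structure and spin-orbit
#' couplings into a `model_system`, the surrogate electronic-structure
#' provider used by all dynamics. The diabatic potential is the standard LVC
#' form: a shared harmonic baseline over all modes plus per-state vertical
#' energies, linear intrastate terms (kappa) and same-spin linear interstate
#' couplings (lambda). Evaluation at the origin reproduces
#' `vertical_energies_eV` exactly (linear terms vanish there).
#'
#' @param electronic An [electronic_spec()].
#' @param modes A modes tibble from [mode_spec()].
#' @param soc An optional [soc_spec()]; `NULL` means zero spin-orbit coupling.
#' @param label Free-text model label.
#' @return A `model_system` object.
#' @examples
#' m <- build_lvc_model(
#'   electronic_spec(2, 1, c(0, 2.96, 2.0), oscillator_strengths = 0.74),
#'   mode_spec(500, 10)
#' )
#' spin_basis_labels(m)
#' @export
build_lvc_model <- function(electronic, modes, soc = NULL, label = "lvc model") {
  stopifnot(inherits(electronic, "electronic_spec"))
  if (!is.null(soc)) stopifnot(inherits(soc, "soc_spec"))
  nS <- electronic$n_singlets
  nT <- electronic$n_triplets
  n_state <- nS + nT
  K <- nrow(modes)
  if (K < 1L) stop("at least one mode is required")

  kap <- electronic$intrastate_gradients_eV
  if (is.null(kap)) kap <- matrix(0, n_state, K)
  kap <- as.matrix(kap)
  if (!all(dim(kap) == c(n_state, K)))
    stop("intrastate_gradients_eV must be a ", n_state, " x ", K, " matrix")

  ## same-spin linear couplings as per-mode block matrices
  lam_S <- array(0, c(nS, nS, K))
  lam_T <- array(0, c(max(nT, 1L), max(nT, 1L), K))
  ic <- electronic$interstate_couplings
  if (!is.null(ic) && nrow(ic) > 0) {
    ia <- scalar_index(ic$state_a, nS, nT)
    ib <- scalar_index(ic$state_b, nS, nT)
    km <- match(ic$mode, modes$label)
    if (anyNA(km)) stop("interstate coupling references unknown mode label")
    for (r in seq_len(nrow(ic))) {
      a <- ia[r]; b <- ib[r]; k <- km[r]; v <- ic$value_eV[r]
      if (a == b) stop("interstate couplings must be off-diagonal")
      both_s <- a <= nS && b <= nS
      both_t <- a > nS && b > nS
      if (!both_s && !both_t)
        stop("interstate (same-spin) couplings cannot mix singlets and triplets; use soc_spec")
      if (both_s) {
        lam_S[a, b, k] <- lam_S[a, b, k] + v
        lam_S[b, a, k] <- lam_S[b, a, k] + v
      } else {
        lam_T[a - nS, b - nS, k] <- lam_T[a - nS, b - nS, k] + v
        lam_T[b - nS, a - nS, k] <- lam_T[b - nS, a - nS, k] + v
      }
    }
  }

  ## SOC base matrix: rows singlets, cols triplet components (t-major, ms -1,0,+1)
  soc_base <- matrix(0 + 0i, nS, 3L * nT)
  mod_tab <- NULL
  if (!is.null(soc) && nT > 0L && nrow(soc$couplings) > 0) {
    sc <- soc$couplings
    si <- scalar_index(sc$singlet, nS, nT)
    ti <- scalar_index(sc$triplet, nS, nT) - nS
    if (any(si > nS) || any(ti < 1L))
      stop("soc couplings must pair a singlet with a triplet")
    col <- (ti - 1L) * 3L + match(sc$component, c(-1L, 0L, 1L))
    for (r in seq_len(nrow(sc)))
      soc_base[si[r], col[r]] <- complex(real = sc$re_cm1[r], imaginary = sc$im_cm1[r])
    if (!is.null(soc$modulation) && nrow(soc$modulation) > 0) {
      mt <- soc$modulation
      mt$row <- scalar_index(mt$singlet, nS, nT)
      mt$col <- (scalar_index(mt$triplet, nS, nT) - nS - 1L) * 3L +
        match(mt$component, c(-1L, 0L, 1L))
      mt$mode_idx <- match(mt$coordinate, modes$label)
      if (anyNA(mt$mode_idx))
        stop("soc modulation coordinate not resolvable: ",
             paste(unique(mt$coordinate[is.na(mt$mode_idx)]), collapse = ", "))
      mod_tab <- mt
    }
  }

  internal <- list(
    omega_au = cm1_to_au(modes$frequency_cm1),
    mass_au = amu_to_au(modes$reduced_mass_amu),
    q0 = modes$equilibrium,
    e0_au = ev_to_au(electronic$vertical_energies_eV),
    kappa_au = ev_to_au(kap),
    lam_S_au = ev_to_au(lam_S),
    lam_T_au = ev_to_au(lam_T),
    soc_base_au = soc_base * .const$cm1_hartree,
    mod_tab = mod_tab,
    dim = nS + 3L * nT
  )

  structure(list(modes = modes, electronic = electronic, soc = soc,
                 label = label, internal = internal),
            class = "model_system")
}

#' @export
print.model_system <- function(x, ...) {
  el <- x$electronic
  cat("<model_system> ", x$label, "\n",
      "  ", el$n_singlets, " singlets + ", el$n_triplets, " triplets ",
      "(spin-diabatic dimension ", x$internal$dim, "), ",
      nrow(x$modes), " mode(s)\n", sep = "")
  invisible(x)
}

## --- internal evaluation in atomic units -----------------------------------

## diabatic blocks and their analytic derivatives at coordinates q (a.u.)
lvc_diabatic_au <- function(model, q) {
  it <- model$internal
  nS <- model$electronic$n_singlets
  nT <- model$electronic$n_triplets
  dq <- q - it$q0
  v_harm <- sum(0.5 * it$mass_au * it$omega_au^2 * dq^2)
  diag_e <- it$e0_au + as.vector(it$kappa_au %*% dq) + v_harm
  V_S <- diag(diag_e[seq_len(nS)], nrow = nS)
  for (k in seq_along(dq)) V_S <- V_S + it$lam_S_au[, , k] * dq[k]
  V_T <- NULL
  if (nT > 0L) {
    V_T <- diag(diag_e[nS + seq_len(nT)], nrow = nT)
    for (k in seq_along(dq)) V_T <- V_T + it$lam_T_au[, , k] * dq[k]
  }
  list(V_S = V_S, V_T = V_T, dq = dq, v_harm = v_harm)
}

## SOC (diabatic, a.u.) with magnitude modulation applied at coordinates q
soc_diabatic_au <- function(model, q) {
  it <- model$internal
  soc <- it$soc_base_au
  mt <- it$mod_tab
  if (!is.null(mt)) {
    dq <- q - it$q0
    for (r in seq_len(nrow(mt))) {
      d <- dq[mt$mode_idx[r]]
      add <- (mt$linear_cm1[r] * d + mt$quadratic_cm1[r] * d^2) * .const$cm1_hartree
      base <- soc[mt$row[r], mt$col[r]]
      mag <- Mod(base)
      soc[mt$row[r], mt$col[r]] <-
        if (mag > 0) base * (mag + add) / mag else complex(real = add)
    }
  }
  soc
}

## ascending symmetric eigendecomposition
eig_asc <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  idx <- order(e$values)
  list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE])
}

## full scalar-basis evaluation: energies, rotations, rotated SOC (a.u.)
eval_scalar_au <- function(model, q) {
  nS <- model$electronic$n_singlets
  nT <- model$electronic$n_triplets
  dia <- lvc_diabatic_au(model, q)
  es <- eig_asc(dia$V_S)
  if (nT > 0L) {
    et <- eig_asc(dia$V_T)
    soc_d <- soc_diabatic_au(model, q)
    soc_s <- crossprod(es$vectors, soc_d) %*% kronecker(et$vectors, diag(3))
    list(e_S = es$values, e_T = et$values, R_S = es$vectors, R_T = et$vectors,
         soc_scalar = soc_s, dia = dia)
  } else {
    list(e_S = es$values, e_T = numeric(), R_S = es$vectors, R_T = NULL,
         soc_scalar = NULL, dia = dia)
  }
}

## Hellmann-Feynman gradients of the scalar (spin-free adiabatic) energies
scalar_gradients_au <- function(model, q, ev) {
  it <- model$internal
  nS <- model$electronic$n_singlets
  nT <- model$electronic$n_triplets
  K <- length(q)
  dq <- q - it$q0
  g <- matrix(0, nS + nT, K)
  for (k in seq_len(K)) {
    harm_k <- it$mass_au[k] * it$omega_au[k]^2 * dq[k]
    dV_S <- diag(it$kappa_au[seq_len(nS), k] + harm_k, nrow = nS) + it$lam_S_au[, , k]
    g[seq_len(nS), k] <- colSums(ev$R_S * (dV_S %*% ev$R_S))
    if (nT > 0L) {
      dV_T <- diag(it$kappa_au[nS + seq_len(nT), k] + harm_k, nrow = nT) +
        it$lam_T_au[, , k]
      g[nS + seq_len(nT), k] <- colSums(ev$R_T * (dV_T %*% ev$R_T))
    }
  }
  g
}

## --- exported evaluation contract -------------------------------------------

#' Evaluate a model at given nuclear coordinates
#'
#' Returns the scalar (spin-free) state energies in the spin-diabatic basis,
#' their analytic gradients, the spin-orbit coupling matrix rotated into the
#' scalar eigenbasis, and the oscillator strengths. The three components of
#' each triplet share the same scalar energy; gradients are exact
#' Hellmann-Feynman derivatives of the returned energies.
#'
#' @param model A `model_system`.
#' @param coords Numeric coordinate vector (atomic units), one per mode.
#' @return A list with `energies_eV` (length `n_singlets + 3 n_triplets`),
#'   `gradients_eV` (same rows x modes, eV per unit coordinate),
#'   `soc_cm1` (complex Hermitian `d x d` matrix, zero same-spin blocks) and
#'   `oscillator_strengths`.
#' @export
evaluate_model <- function(model, coords) {
  stopifnot(inherits(model, "model_system"))
  coords <- as.numeric(coords)
  if (length(coords) != nrow(model$modes))
    stop("coords length must equal the number of modes")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  nS <- model$electronic$n_singlets
  nT <- model$electronic$n_triplets
  d <- model$internal$dim
  ev <- eval_scalar_au(model, coords)
  g_scalar <- scalar_gradients_au(model, coords, ev)
  expand <- c(seq_len(nS), if (nT > 0L) nS + rep(seq_len(nT), each = 3L))
  e_full <- c(ev$e_S, if (nT > 0L) rep(ev$e_T, each = 3L))
  soc_full <- matrix(0 + 0i, d, d)
  if (nT > 0L && !is.null(ev$soc_scalar)) {
    soc_full[seq_len(nS), nS + seq_len(3L * nT)] <- ev$soc_scalar
    soc_full[nS + seq_len(3L * nT), seq_len(nS)] <- Conj(t(ev$soc_scalar))
  }
  list(
    energies_eV = au_to_ev(e_full),
    gradients_eV = au_to_ev(g_scalar[expand, , drop = FALSE]),
    soc_cm1 = soc_full / .const$cm1_hartree,
    oscillator_strengths = model$electronic$oscillator_strengths
  )
}

#' Geometry-dependent spin-orbit coupling matrix
#'
#' Evaluates the configured SOC magnitude modulation at the given coordinates
#' and returns the diabatic singlet-triplet coupling block. At the reference
#' geometry (all coordinates at their equilibria) this equals the base SOC
#' exactly; even (quadratic) modulation yields equal magnitudes at symmetric
#' displacements.
#'
#' @param model A `model_system`.
#' @param coords Numeric coordinate vector, one per mode.
#' @return Complex matrix `n_singlets x 3 n_triplets` in cm^-1 (rows:
#'   singlets; columns: triplet components, M_S = -1, 0, +1 per triplet).
#' @export
soc_modulation <- function(model, coords) {
  stopifnot(inherits(model, "model_system"))
  coords <- as.numeric(coords)
  if (length(coords) != nrow(model$modes))
    stop("coords length must equal the number of modes")
  soc_diabatic_au(model, coords) / .const$cm1_hartree
}
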