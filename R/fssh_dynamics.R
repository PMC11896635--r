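#' Dynamics parameters for spin-adiabatic surface hopping
#'
#' Defaults follow the standard accelerated-ISC protocol: 0.5 fs nuclear
#' step, 20 electronic substeps (0.025 fs), 200 fs horizon, trajectories
#' started from the spin-adiabatic state with maximal overlap with S1. No
#' decoherence correction is applied anywhere (the coefficient vector is
#' never damped).
#'
#' @param dt_fs Nuclear time step (fs), > 0. Default 0.5.
#' @param n_substeps Electronic substeps per nuclear step, >= 1. Default 20.
#' @param t_max_fs Maximum simulation time (fs). Default 200.
#' @param alpha SOC scaling factor, >= 0. Default 1.
#' @param initial_state Spin-diabatic label to start from. Default "S1".
#' @param seed Integer RNG seed for the hopping rolls.
#' @return A list of class `dynamics_params`.
#' @export
dynamics_params <- function(dt_fs = 0.5, n_substeps = 20L, t_max_fs = 200,
                            alpha = 1, initial_state = "S1", seed = 1L) {
  if (dt_fs <= 0) stop("dt_fs must be > 0")
  if (n_substeps < 1L) stop("n_substeps must be >= 1")
  if (t_max_fs < dt_fs) stop("t_max_fs must be >= dt_fs")
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(dt_fs = dt_fs, n_substeps = as.integer(n_substeps),
                 t_max_fs = t_max_fs, alpha = alpha,
                 initial_state = initial_state, seed = as.integer(seed),
                 decoherence = "none"),
            class = "dynamics_params")
}

## --- internal helpers -------------------------------------------------------

## per-mode derivative blocks of the diabatic Hamiltonian (cached on model)
deriv_blocks <- function(model) {
  it <- model$internal
  nS <- model$electronic$n_singlets
  nT <- model$electronic$n_triplets
  K <- length(it$omega_au)
  A_S <- lapply(seq_len(K), function(k)
    diag(it$kappa_au[seq_len(nS), k], nrow = nS) + it$lam_S_au[, , k])
  A_T <- if (nT > 0L) lapply(seq_len(K), function(k)
    diag(it$kappa_au[nS + seq_len(nT), k], nrow = nT) + it$lam_T_au[, , k]) else NULL
  list(A_S = A_S, A_T = A_T)
}

## dSOC/dq_k (diabatic, a.u.) from the modulation table; NULL when absent
soc_deriv_au <- function(model, q, k) {
  mt <- model$internal$mod_tab
  if (is.null(mt)) return(NULL)
  rows <- which(mt$mode_idx == k)
  if (length(rows) == 0L) return(NULL)
  nS <- model$electronic$n_singlets
  dmat <- matrix(0 + 0i, nS, 3L * model$electronic$n_triplets)
  dq <- q - model$internal$q0
  for (r in rows) {
    d <- dq[mt$mode_idx[r]]
    dmag <- (mt$linear_cm1[r] + 2 * mt$quadratic_cm1[r] * d) * .const$cm1_hartree
    base <- model$internal$soc_base_au[mt$row[r], mt$col[r]]
    ph <- if (Mod(base) > 0) base / Mod(base) else 1 + 0i
    dmat[mt$row[r], mt$col[r]] <- ph * dmag
  }
  dmat
}

## force (a.u.) on the active spin-adiabatic surface: exact Hellmann-Feynman
## gradient of u' H u in the coordinate-independent diabatic basis.
active_force_au <- function(model, q, ev, u, alpha, dblocks) {
  it <- model$internal
  nS <- model$electronic$n_singlets
  nT <- model$electronic$n_triplets
  wS <- ev$R_S %*% u[seq_len(nS)]
  WT <- NULL
  if (nT > 0L) {
    uT <- u[nS + seq_len(3L * nT)]
    ## (R_T kron I3) u  ==  vec( mat3(u) t(R_T) )
    WT <- matrix(uT, nrow = 3L) %*% t(ev$R_T)
  }
  dq <- q - it$q0
  K <- length(q)
  f <- numeric(K)
  for (k in seq_len(K)) {
    ## harmonic baseline is shared by every state: contributes with weight 1
    harm <- it$mass_au[k] * it$omega_au[k]^2 * dq[k]
    g <- harm + Re(sum(Conj(wS) * (dblocks$A_S[[k]] %*% wS)))
    if (nT > 0L) {
      g <- g + Re(sum(Conj(WT) * (WT %*% t(dblocks$A_T[[k]]))))
      dsoc <- soc_deriv_au(model, q, k)
      if (!is.null(dsoc))
        g <- g + 2 * alpha * Re(sum(Conj(wS) * (dsoc %*% as.vector(WT))))
    }
    f[k] <- -g
  }
  f
}

## lean gauge alignment for the propagation loop: identity-permutation fast
## path when diagonal overlaps dominate, greedy assignment otherwise
align_fast <- function(U_prev, S, U_curr, E_curr) {
  O <- Conj(t(U_prev)) %*% S %*% U_curr
  dO <- Mod(diag(O))
  if (all(dO > 0.7071)) {
    ph <- Conj(diag(O)) / dO
    U <- sweep(U_curr, 2, ph, "*")
    return(list(U = U, E = E_curr, O = sweep(O, 2, ph, "*")))
  }
  d <- ncol(O)
  absO <- Mod(O)
  perm <- integer(d)
  taken <- rep(FALSE, d)
  for (i in order(apply(absO, 1, max), decreasing = TRUE)) {
    j <- which.max(ifelse(taken, -1, absO[i, ]))
    perm[i] <- j; taken[j] <- TRUE
  }
  U <- U_curr[, perm, drop = FALSE]
  O <- O[, perm, drop = FALSE]
  dg <- diag(O); m <- Mod(dg)
  ph <- ifelse(m > 1e-14, Conj(dg) / m, 1 + 0i)
  list(U = sweep(U, 2, ph, "*"), E = E_curr[perm], O = sweep(O, 2, ph, "*"))
}

## block-diagonal scalar-basis overlap between consecutive geometries
scalar_overlap <- function(ev_prev, ev_curr, nT) {
  S_s <- crossprod(ev_prev$R_S, ev_curr$R_S)
  if (nT > 0L) {
    S_t <- kronecker(crossprod(ev_prev$R_T, ev_curr$R_T), diag(3))
    d <- nrow(S_s) + nrow(S_t)
    S <- matrix(0, d, d)
    S[seq_len(nrow(S_s)), seq_len(nrow(S_s))] <- S_s
    S[nrow(S_s) + seq_len(nrow(S_t)), nrow(S_s) + seq_len(nrow(S_t))] <- S_t
    S
  } else S_s
}

spin_diag <- function(ev, nT, alpha) {
  e_full <- c(ev$e_S, if (nT > 0L) rep(ev$e_T, each = 3L))
  d <- length(e_full)
  H <- matrix(0 + 0i, d, d)
  diag(H) <- e_full
  if (nT > 0L) {
    nS <- length(ev$e_S)
    H[seq_len(nS), nS + seq_len(3L * nT)] <- alpha * ev$soc_scalar
    H[nS + seq_len(3L * nT), seq_len(nS)] <- alpha * Conj(t(ev$soc_scalar))
  }
  e <- eigen(H, symmetric = TRUE)
  idx <- order(e$values)
  V <- e$vectors[, idx, drop = FALSE]
  if (!is.complex(V)) V <- matrix(as.complex(V), nrow = d)
  list(E = e$values[idx], U = V)
}

## --- exported single-step operations ---------------------------------------

#' One velocity-Verlet nuclear step on the active spin-adiabatic surface
#'
#' Advances coordinates and momenta by one time step using the analytic
#' force on the active spin-adiabatic surface (Hellmann-Feynman on the model
#' Hamiltonian). Intended for testing and custom integration loops;
#' [run_trajectory()] performs the same update internally.
#'
#' @param state List with `coords`, `momenta` (atomic units) and `active`
#'   (spin-adiabatic index, 1-based, energy-ascending at this geometry).
#' @param model A `model_system`.
#' @param params A [dynamics_params()].
#' @return The updated state (same shape), with `t_fs` advanced.
#' @export
nuclear_step <- function(state, model, params) {
  it <- model$internal
  nT <- model$electronic$n_triplets
  dblocks <- deriv_blocks(model)
  dt <- fs_to_au(params$dt_fs)
  ev <- eval_scalar_au(model, state$coords)
  sd <- spin_diag(ev, nT, params$alpha)
  f <- active_force_au(model, state$coords, ev, sd$U[, state$active], params$alpha, dblocks)
  if (any(!is.finite(f))) stop("non-finite force")
  p_half <- state$momenta + 0.5 * f * dt
  q_new <- state$coords + p_half / it$mass_au * dt
  ev2 <- eval_scalar_au(model, q_new)
  sd2 <- spin_diag(ev2, nT, params$alpha)
  S <- scalar_overlap(ev, ev2, nT)
  U2 <- align_gauge(sd$U, sd2$U, metric = S, energies = sd2$E)
  f2 <- active_force_au(model, q_new, ev2, U2[, state$active], params$alpha, dblocks)
  state$coords <- q_new
  state$momenta <- p_half + 0.5 * f2 * dt
  state$t_fs <- (state$t_fs %||% 0) + params$dt_fs
  state
}

#' Time-derivative couplings from eigenvector overlaps
#'
#' Finite-difference estimate of the antisymmetrized time-derivative
#' coupling matrix
#' \eqn{T_{jk} = (\langle\phi_j(t)|\phi_k(t+dt)\rangle -
#'   \langle\phi_k(t)|\phi_j(t+dt)\rangle)/(2 dt)}
#' from two gauge-aligned unitaries. The result is real antisymmetric by
#' construction.
#'
#' @param U_prev,U_curr Gauge-aligned unitaries at consecutive steps.
#' @param dt_fs Time step between them (fs).
#' @param metric Optional scalar-basis overlap between the two steps.
#' @return Real antisymmetric matrix, units fs^-1.
#' @export
tdc_estimate <- function(U_prev, U_curr, dt_fs, metric = NULL) {
  O <- if (is.null(metric)) Conj(t(U_prev)) %*% U_curr
       else Conj(t(U_prev)) %*% metric %*% U_curr
  if (any(Mod(diag(O)) < 0.5))
    stop("diagonal overlaps far from 1: inputs are not gauge-aligned")
  R <- Re(O)
  (R - t(R)) / (2 * dt_fs)
}

#' Substepped unitary propagation of the electronic coefficients
#'
#' Advances the complex coefficient vector through `n_substeps` exact matrix
#' exponentials with energies and time-derivative couplings linearly
#' interpolated between two consecutive nuclear steps. Unitary to machine
#' precision; no decoherence correction is applied.
#'
#' @param c_coef Complex coefficient vector (spin-adiabatic basis).
#' @param E_prev_eV,E_curr_eV Real energy vectors (eV) at the two steps.
#' @param T_prev,T_curr Real antisymmetric coupling matrices (fs^-1).
#' @param dt_fs Nuclear time step (fs).
#' @param n_substeps Number of substeps (default 20).
#' @return The advanced coefficient vector.
#' @export
electronic_propagate <- function(c_coef, E_prev_eV, E_curr_eV, T_prev, T_curr,
                                 dt_fs, n_substeps = 20L) {
  res <- .propagate_substeps(as.complex(c_coef),
                             ev_to_au(E_prev_eV), ev_to_au(E_curr_eV),
                             T_prev / .const$fs_au, T_curr / .const$fs_au,
                             fs_to_au(dt_fs), as.integer(n_substeps), 0L)
  if (any(!is.finite(Mod(res$c)))) stop("substep matrix exponential failure (non-finite)")
  as.vector(res$c)
}

#' Fewest-switches hopping probabilities
#'
#' Probability of hopping out of the active state into each other state over
#' one step:
#' \eqn{g_{a\to j} = \max\{0, 2\,\mathrm{Re}(T_{aj}\, c_j^* c_a)\,dt /
#'   |c_a|^2\}},
#' the coherent population outflow of the active state attributed to state
#' j (negative flows are clipped to zero, the fewest-switches
#' prescription). If the raw probabilities sum above 1 they are renormalized
#' to sum 1 and a warning is emitted.
#'
#' @param c_coef Complex coefficient vector, approximately normalized.
#' @param T_mat Real antisymmetric coupling matrix (fs^-1).
#' @param active Active state index (1-based).
#' @param dt_fs Time step (fs).
#' @return Numeric vector of per-state probabilities (0 at the active
#'   position), each in \[0, 1\], summing to at most 1.
#' @export
hop_probabilities <- function(c_coef, T_mat, active, dt_fs) {
  d <- length(c_coef)
  g <- numeric(d)
  pa <- Mod(c_coef[active])^2
  if (pa < 1e-12) {
    warning("active-state population below 1e-12; returning zero probabilities")
    return(g)
  }
  for (j in seq_len(d)) {
    if (j == active) next
    g[j] <- max(0, 2 * Re(T_mat[active, j] * Conj(c_coef[j]) * c_coef[active]) *
                  dt_fs / pa)
  }
  tot <- sum(g)
  if (tot > 1) {
    warning("raw hopping probabilities summed to ", signif(tot, 4),
            "; renormalized to 1")
    g <- g / tot
  }
  g
}

#' Energy-conserving surface hop with uniform momentum rescaling
#'
#' Attempts a hop to `target`. If the kinetic energy covers the electronic
#' energy gap, the full momentum vector is rescaled by a single scalar
#' factor so total energy is conserved and the active state switches;
#' otherwise the hop is frustrated: rejected with momenta unchanged (no
#' reversal).
#'
#' @param state List with `coords`, `momenta`, `active` and `energies`
#'   (current spin-adiabatic energies, hartree).
#' @param target Target state index (1-based), different from `active`.
#' @param model A `model_system` (provides the masses).
#' @return The state, plus a `hop` element: list(`from`, `to`, `accepted`).
#' @export
apply_hop <- function(state, target, model) {
  if (target == state$active) stop("target must differ from the active state")
  mass <- model$internal$mass_au
  ke <- sum(state$momenta^2 / (2 * mass))
  gap <- state$energies[target] - state$energies[state$active]
  if (ke >= gap) {
    factor <- sqrt((ke - gap) / ke)
    state$momenta <- state$momenta * factor
    hop <- list(from = state$active, to = target, accepted = TRUE)
    state$active <- target
  } else {
    hop <- list(from = state$active, to = target, accepted = FALSE)
  }
  state$hop <- hop
  state
}

## --- full trajectory --------------------------------------------------------

#' Run one surface-hopping trajectory
#'
#' Propagates a mixed quantum-classical trajectory: velocity-Verlet nuclear
#' motion on the active spin-adiabatic surface, diagonalization and gauge
#' alignment at every new geometry, substepped unitary electronic
#' propagation with linearly interpolated energies and couplings, and
#' fewest-switches hops with uniform energy-conserving momentum rescaling.
#' The trajectory starts in the spin-adiabatic state with maximal overlap
#' with the requested spin-diabatic state; the coefficient vector is
#' initialized as that basis vector. Deterministic given (model, sample,
#' params).
#'
#' @param model A `model_system`.
#' @param sample Initial conditions: a single-row tibble from
#'   [sample_wigner()] or a list with `coords` and `momenta` (atomic units).
#' @param params A [dynamics_params()].
#' @return An object of class `trajectory`: `times_fs`, `coords`, `momenta`
#'   (step x mode matrices), `active`, `pop_adiabatic` (|c|^2),
#'   `pop_diabatic` (|b|^2, triplet components summed, step x scalar-state),
#'   `hops` (tibble: `t_fs`, `from`, `to`, `from_label`, `to_label`,
#'   `accepted`, and the unitary at the hop in `U`), `energy` (tibble with
#'   potential/kinetic/total, eV), `state_labels`, `params`, `n_renorm`.
#' @export
run_trajectory <- function(model, sample, params) {
  if (is.data.frame(sample)) sample <- list(coords = sample$coords[[1]],
                                            momenta = sample$momenta[[1]])
  q <- as.numeric(sample$coords)
  p <- as.numeric(sample$momenta)
  it <- model$internal
  nS <- model$electronic$n_singlets
  nT <- model$electronic$n_triplets
  dt <- fs_to_au(params$dt_fs)
  n_steps <- floor(params$t_max_fs / params$dt_fs + 1e-9)
  labels <- scalar_labels(model)

  init_idx <- match(params$initial_state, labels)
  if (is.na(init_idx)) stop("unknown initial state: ", params$initial_state)
  ## spin-basis row of the requested state (ms = 0 component for a triplet)
  row0 <- if (init_idx <= nS) init_idx else nS + (init_idx - nS - 1L) * 3L + 2L

  mt <- it$mod_tab
  mod_mat <- if (is.null(mt)) matrix(0, 0, 5) else
    cbind(mt$row, mt$col, mt$mode_idx,
          mt$linear_cm1 * .const$cm1_hartree,
          mt$quadratic_cm1 * .const$cm1_hartree)
  model_au <- list(
    omega = it$omega_au, mass = it$mass_au, q0 = it$q0, e0 = it$e0_au,
    kappa = it$kappa_au, lamS = it$lam_S_au,
    lamT = if (nT > 0L) it$lam_T_au else array(0, c(1, 1, length(it$omega_au))),
    soc = it$soc_base_au, mod = mod_mat, nS = nS, nT = nT
  )

  withr::local_seed(params$seed)
  res <- .run_lvc_trajectory(model_au, q, p, row0, params$alpha, dt,
                             params$n_substeps, n_steps)

  times_fs <- as.vector(res$times_au) / .const$fs_au
  hops_tbl <- tibble::tibble(
    t_fs = as.numeric(res$hop_t) / .const$fs_au,
    from = as.integer(res$hop_from),
    to = as.integer(res$hop_to),
    accepted = as.logical(res$hop_accepted),
    U = res$hop_U
  )
  pot <- au_to_ev(as.vector(res$potential))
  kin <- au_to_ev(as.vector(res$kinetic))
  structure(list(
    times_fs = times_fs,
    coords = res$coords, momenta = res$momenta,
    active = as.integer(res$active),
    pop_adiabatic = res$pop_adiabatic,
    pop_diabatic = res$pop_diabatic,
    energy = tibble::tibble(t_fs = times_fs, potential_eV = pot,
                            kinetic_eV = kin, total_eV = pot + kin),
    hops = hops_tbl, state_labels = labels, params = params,
    n_renorm = res$n_renorm, truncated = res$truncated
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times_fs), " steps to ",
      max(x$times_fs), " fs; alpha = ", x$params$alpha,
      "; ", sum(x$hops$accepted), " accepted hop(s)",
      if (x$truncated) "; TRUNCATED (non-finite propagation)", "\n", sep = "")
  invisible(x)
}

#' Run surface-hopping ensembles over a set of SOC scaling factors
#'
#' For each alpha, runs one trajectory per Wigner sample with an
#' independently derived RNG stream (base seed, alpha index, trajectory
#' index), so ensembles are reproducible and order-independent.
#'
#' @param model A `model_system`.
#' @param samples Tibble from [sample_wigner()].
#' @param params A [dynamics_params()]; its `alpha` is overridden per set.
#' @param alphas Numeric vector of SOC scaling factors (default the
#'   standard protocol `c(2, 3.5, 5)`).
#' @param t_max_fs Optional per-alpha horizon(s), recycled over `alphas`
#'   (the standard protocol uses 200, 200 and 100 fs).
#' @param progress Emit a message per completed ensemble.
#' @return Named list (one element per alpha, named by its value) of lists
#'   of `trajectory` objects.
#' @export
run_ensemble <- function(model, samples, params, alphas = c(2, 3.5, 5),
                         t_max_fs = NULL, progress = FALSE) {
  if (length(alphas) == 0L) return(stats::setNames(list(), character()))
  if (nrow(samples) < 1L) stop("at least one sample is required")
  if (is.null(t_max_fs)) t_max_fs <- params$t_max_fs
  t_max_fs <- rep_len(t_max_fs, length(alphas))
  out <- vector("list", length(alphas))
  names(out) <- as.character(alphas)
  for (ai in seq_along(alphas)) {
    pa <- params
    pa$alpha <- alphas[ai]
    pa$t_max_fs <- t_max_fs[ai]
    trajs <- vector("list", nrow(samples))
    for (i in seq_len(nrow(samples))) {
      pa$seed <- derive_seed(derive_seed(params$seed, 100000L + ai), i)
      trajs[[i]] <- run_trajectory(model, samples[i, ], pa)
    }
    if (progress)
      message("alpha = ", alphas[ai], ": ", length(trajs), " trajectories done")
    out[[ai]] <- trajs
  }
  out
}
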