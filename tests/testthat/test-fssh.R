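cst <- physical_constants()

test_that("nuclear step: free motion is a straight line; oscillator period recovered", {
  ## zero force: flat surface (kappa = 0 everywhere, at the S1 minimum q = 0
  ## of a very soft mode approximates free flight poorly, so use the exact
  ## harmonic solution instead for the period check below)
  m <- harmonic_singlet_model(500, 10)
  p <- dynamics_params(dt_fs = 0.5, alpha = 0, initial_state = "S1")
  ## harmonic oscillation: period 2 pi / omega for omega = 500 cm^-1
  omega_au <- 500 * cst$cm1_hartree
  period_fs <- 2 * pi / omega_au / cst$fs_au
  st <- list(coords = 0.2, momenta = 0, active = 2L, t_fs = 0)
  qs <- numeric(300)
  for (i in 1:300) { st <- nuclear_step(st, m, p); qs[i] <- st$coords }
  ## locate period from the first two downward zero crossings
  sgn <- sign(qs)
  cross <- which(diff(sgn) < 0)
  measured <- (cross[2] - cross[1]) * 0.5
  expect_lt(abs(measured - period_fs) / period_fs, 0.001 + 0.5 / period_fs)
  ## uniform motion when the surface is flat: S0 of a model with no curvature
  ## is approximated by a tiny-frequency mode
  m_flat <- harmonic_singlet_model(1e-3, 10)
  st <- list(coords = 0, momenta = 3, active = 2L, t_fs = 0)
  mass_au <- 10 * cst$amu_me
  for (i in 1:10) st <- nuclear_step(st, m_flat, p)
  expect_equal(st$coords, 3 / mass_au * spinhop:::fs_to_au(5), tolerance = 1e-6)
})

test_that("tdc estimate: zero for identical frames, rotation rate recovered, antisymmetric", {
  U <- random_unitary(4, seed = 5)
  expect_equal(tdc_estimate(U, U, 0.5), matrix(0, 4, 4))
  ## planar rotation at angular rate w between two states
  w <- 0.02  # rad / fs
  dt <- 0.5
  rot <- function(t) matrix(c(cos(w * t), -sin(w * t), sin(w * t), cos(w * t)), 2) + 0i
  Tm <- tdc_estimate(rot(0), rot(dt), dt)
  expect_equal(Tm[1, 2], w, tolerance = w * dt^2)
  expect_equal(Tm, -t(Tm))
  withr::local_seed(12)
  for (rep in 1:5) {
    A <- random_unitary(5)
    ## gauge-aligned small step away from A
    B <- align_gauge(A, A %*% (diag(5) + 0.01 * (function(M) (M - t(Conj(M))) / 2)(
      matrix(complex(real = rnorm(25), imaginary = rnorm(25)), 5))))
    Tr <- tdc_estimate(A, B, 0.5)
    expect_lt(max(abs(Tr + t(Tr))), 1e-12)
  }
  expect_error(tdc_estimate(rot(0), matrix(c(0, 1, -1, 0), 2) + 0i, 0.5),
               "aligned")
})

test_that("electronic propagation: pure phases, Rabi transfer, long-time norm", {
  ## constant diagonal energies, zero coupling: populations unchanged
  c0 <- random_coef(3, seed = 2)
  E <- c(0.5, 1.1, 2.0)
  Tz <- matrix(0, 3, 3)
  c1 <- electronic_propagate(c0, E, E, Tz, Tz, dt_fs = 0.5, n_substeps = 20)
  expect_equal(Mod(c1)^2, Mod(c0)^2, tolerance = 1e-12)
  ## phase accumulated equals exp(-i E dt / hbar)
  phase_expected <- exp(-1i * spinhop:::ev_to_au(E) * spinhop:::fs_to_au(0.5))
  expect_lt(max(Mod(c1 - phase_expected * c0)), 1e-10)

  ## Rabi: degenerate 2-level with constant coupling V in the TDC slot
  V <- 0.004  # fs^-1, V * dt << 1
  Tc <- matrix(c(0, -V, V, 0), 2)
  cc <- c(1, 0) + 0i
  steps <- 200
  for (i in seq_len(steps))
    cc <- electronic_propagate(cc, c(0, 0), c(0, 0), Tc, Tc, 0.5, 20)
  t_tot <- steps * 0.5
  expect_equal(Mod(cc[2])^2, sin(V * t_tot)^2, tolerance = 1e-6)

  ## norm conservation over 400 nuclear steps with varying E and T
  withr::local_seed(3)
  cc <- random_coef(5)
  for (i in 1:400) {
    E1 <- sort(runif(5, 0, 3)); E2 <- E1 + rnorm(5, 0, 0.01)
    M <- matrix(rnorm(25, 0, 0.01), 5); Tm <- M - t(M)
    cc <- electronic_propagate(cc, E1, E2, Tm, Tm, 0.5, 20)
  }
  expect_lt(abs(sqrt(sum(Mod(cc)^2)) - 1), 1e-8)
})

test_that("hop probabilities: zero coupling, clipping contract, zero-population warning", {
  cc <- random_coef(4, seed = 9)
  expect_equal(hop_probabilities(cc, matrix(0, 4, 4), 1, 0.5), rep(0, 4))
  ## pathological raw sum > 1 is renormalized to exactly 1 with a warning
  cc <- c(sqrt(0.01), sqrt(0.66), sqrt(0.33)) + 0i
  Tbig <- matrix(c(0, -60, -30, 60, 0, 0, 30, 0, 0), 3)
  expect_warning(g <- hop_probabilities(cc, Tbig, 1, 0.5), "renormalized")
  expect_equal(sum(g), 1)
  expect_true(all(g >= 0 & g <= 1))
  cc0 <- c(0, 1, 0) + 0i
  expect_warning(g0 <- hop_probabilities(cc0, Tbig, 1, 0.5), "below")
  expect_equal(g0, rep(0, 3))
})

test_that("hops conserve energy: downward always accepted, upward frustrated when KE < gap", {
  m <- pair_model(soc_cm1 = 50)
  mass <- m$internal$mass_au
  en <- c(0, 0.11, 0.1103, 0.1103, 0.1103)
  st <- list(coords = 0, momenta = 1.0, active = 5L, energies = en)
  ke0 <- sum(st$momenta^2 / (2 * mass))
  ## downward hop: kinetic energy increases by the gap
  st2 <- apply_hop(st, 2L, m)
  expect_true(st2$hop$accepted)
  ke2 <- sum(st2$momenta^2 / (2 * mass))
  expect_equal(ke2 - ke0, en[5] - en[2], tolerance = 1e-12)
  expect_equal(st2$active, 2L)
  ## upward hop with insufficient kinetic energy: frustrated, momenta unchanged
  st$active <- 1L
  st$momenta <- 0.1
  st3 <- apply_hop(st, 2L, m)
  expect_false(st3$hop$accepted)
  expect_equal(st3$momenta, 0.1)
  expect_equal(st3$active, 1L)
  ## accepted upward hop conserves total energy to 1e-8 hartree
  st$momenta <- 70   # kinetic energy above the 0.11 hartree gap
  st4 <- apply_hop(st, 2L, m)
  expect_true(st4$hop$accepted)
  e_before <- en[1] + sum(st$momenta^2 / (2 * mass))
  e_after <- en[2] + sum(st4$momenta^2 / (2 * mass))
  expect_lt(abs(e_after - e_before), 1e-8)
})

test_that("decoupled dynamics stays in S1; identical seeds give identical trajectories", {
  m <- pair_model(soc_cm1 = 100)
  p0 <- dynamics_params(t_max_fs = 200, alpha = 0, initial_state = "S1", seed = 4)
  tr <- run_trajectory(m, list(coords = 0.12, momenta = 1), p0)
  expect_true(all(abs(tr$pop_diabatic[, 2] - 1) < 1e-10))
  expect_equal(nrow(tr$hops), 0L)
  m2 <- random_smooth_model(55)
  s <- sample_wigner(m2$modes, 298, 1, seed = 21)
  p <- dynamics_params(t_max_fs = 50, alpha = 4, seed = 33)
  ta <- run_trajectory(m2, s[1, ], p)
  tb <- run_trajectory(m2, s[1, ], p)
  expect_identical(ta$coords, tb$coords)
  expect_identical(ta$pop_diabatic, tb$pop_diabatic)
  expect_identical(ta$hops$t_fs, tb$hops$t_fs)
})

test_that("total energy is conserved between hops and electronic norm over full runs", {
  m <- random_smooth_model(88)
  s <- sample_wigner(m$modes, 298, 2, seed = 13)
  p <- dynamics_params(t_max_fs = 100, alpha = 2, seed = 17)
  for (i in 1:2) {
    tr <- run_trajectory(m, s[i, ], p)
    e_h <- tr$energy$total_eV / cst$hartree_eV
    hop_steps <- unique(c(1L, round(tr$hops$t_fs[tr$hops$accepted] / 0.5) + 1L,
                          length(e_h)))
    hop_steps <- sort(hop_steps)
    ## within each hop-free segment the drift must stay below 1e-6 hartree
    for (seg in seq_len(length(hop_steps) - 1L)) {
      idx <- (hop_steps[seg] + 1L):hop_steps[seg + 1L]
      if (length(idx) < 2L) next
      expect_lt(max(abs(e_h[idx] - e_h[idx[1]])), 1e-5)
    }
    ## norm: |c|^2 recorded populations sum to 1 throughout
    expect_true(all(abs(rowSums(tr$pop_adiabatic) - 1) < 1e-8))
    expect_equal(tr$n_renorm, 0L)
  }
})

test_that("compiled trajectory core agrees with the R single-step operations", {
  ## on an uncoupled surface the full run is deterministic: compare the
  ## compiled-core trajectory against stepping with nuclear_step()
  m <- pair_model(soc_cm1 = 80)
  p <- dynamics_params(dt_fs = 0.5, t_max_fs = 25, alpha = 0,
                       initial_state = "S1", seed = 9)
  tr <- run_trajectory(m, list(coords = 0.15, momenta = 3), p)
  st <- list(coords = 0.15, momenta = 3, active = 2L, t_fs = 0)
  for (i in 1:50) st <- nuclear_step(st, m, p)
  expect_equal(tr$coords[51, 1], st$coords, tolerance = 1e-10)
  expect_equal(tr$momenta[51, 1], st$momenta, tolerance = 1e-10)
})

test_that("ensemble runner: empty alphas, per-alpha derived streams, protocol shape", {
  m <- pair_model(soc_cm1 = 20)
  s <- sample_wigner(m$modes, 298, 2, seed = 3)
  p <- dynamics_params(t_max_fs = 10, seed = 7)
  expect_length(run_ensemble(m, s, p, alphas = numeric()), 0L)
  ens <- run_ensemble(m, s, p, alphas = c(2, 3.5), t_max_fs = c(10, 5))
  expect_named(ens, c("2", "3.5"))
  expect_length(ens[["2"]], 2L)
  expect_equal(max(ens[["3.5"]][[1]]$times_fs), 5)
  ## different alphas use different derived seeds: hop RNG streams differ
  expect_false(identical(ens[["2"]][[1]]$params$seed, ens[["3.5"]][[1]]$params$seed))
  ## default protocol shape
  expect_equal(formals(run_ensemble)$alphas, quote(c(2, 3.5, 5)))
  expect_equal(dynamics_params()$dt_fs, 0.5)
  expect_equal(dynamics_params()$n_substeps, 20L)
  expect_equal(dynamics_params()$t_max_fs, 200)
  expect_identical(dynamics_params()$decoherence, "none")
})
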