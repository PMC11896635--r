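cm1_h <- physical_constants()$cm1_hartree

test_that("alpha scales only the SOC blocks; alpha = 0 decouples the manifolds", {
  d <- 5
  soc <- matrix(0 + 0i, d, d)
  soc[1, 3:5] <- complex(real = c(1, 2, 3), imaginary = c(-1, 0, 2)) * 1e-4
  soc[3:5, 1] <- Conj(soc[1, 3:5])
  en <- c(0, 0.1, 0.11, 0.11, 0.11)
  H0 <- assemble_spin_hamiltonian(en, soc, alpha = 0)
  expect_equal(unclass(H0), diag(en) + 0i, ignore_attr = TRUE)
  H2 <- assemble_spin_hamiltonian(en, soc, alpha = 2)
  expect_equal(H2[1, 3], 2 * soc[1, 3])
  expect_equal(diag(H2), as.complex(en))
  expect_error(assemble_spin_hamiltonian(en, soc * 0 + 1i * 1e-3), "Hermitian")
})

test_that("a 7-singlet, 10-triplet system assembles to dimension 37", {
  d <- 7 + 3 * 10
  H <- assemble_spin_hamiltonian(seq_len(d) * 0.01, matrix(0 + 0i, d, d), 1)
  expect_equal(dim(H), c(37L, 37L))
})

test_that("diagonalization: zero SOC returns sorted scalar energies, signed permutation", {
  en <- c(0.3, 0.1, 0.2)
  qs <- diagonalize_spin_hamiltonian(
    assemble_spin_hamiltonian(en, matrix(0 + 0i, 3, 3), 1))
  expect_equal(qs$energies, sort(en))
  expect_true(all(abs(abs(Re(qs$vectors)) + abs(Im(qs$vectors)) - (Mod(qs$vectors) > 0.5)) < 1e-12))
  # unitarity and reconstruction
  U <- qs$vectors
  expect_lt(max(Mod(Conj(t(U)) %*% U - diag(3))), 1e-10)
})

test_that("degenerate S/T pair coupled by lambda splits to +/- lambda, linear in alpha", {
  lambda_h <- 100 * cm1_h
  E0 <- 0.11
  soc <- matrix(0 + 0i, 2, 2)
  soc[1, 2] <- lambda_h; soc[2, 1] <- lambda_h
  for (a in c(1, 2)) {
    qs <- diagonalize_spin_hamiltonian(
      assemble_spin_hamiltonian(c(E0, E0), soc, alpha = a))
    expect_equal(qs$energies, E0 + a * c(-lambda_h, lambda_h), tolerance = 1e-12)
  }
})

test_that("eigendecomposition residual and unitarity hold on random Hermitian input", {
  withr::local_seed(31)
  for (rep in 1:5) {
    d <- sample(3:12, 1)
    A <- matrix(complex(real = rnorm(d * d), imaginary = rnorm(d * d)), d)
    H <- (A + Conj(t(A))) / 2
    qs <- diagonalize_spin_hamiltonian(H)
    U <- qs$vectors
    expect_lt(max(Mod(Conj(t(U)) %*% U - diag(d))), 1e-10)
    res <- H %*% U - U %*% diag(qs$energies)
    expect_lt(max(Mod(res)), 1e-9 * max(Mod(H)))
    expect_false(is.unsorted(qs$energies))
  }
})

test_that("align_gauge removes pure phase gauge and undoes column swaps", {
  U <- random_unitary(4, seed = 3)
  ph <- exp(1i * c(0.3, -1.2, 2.5, 0.9))
  out <- align_gauge(U, U %*% diag(ph))
  expect_lt(max(Mod(out - U)), 1e-12)
  expect_equal(attr(out, "permutation"), 1:4)
  # column swap detected and undone
  perm <- c(2, 1, 4, 3)
  out2 <- align_gauge(U, U[, perm])
  expect_lt(max(Mod(out2 - U)), 1e-12)
  # identity action
  out3 <- align_gauge(U, U)
  expect_lt(max(Mod(out3 - U)), 1e-12)
})

test_that("align_gauge matching agrees with brute-force permutation search (d <= 6)", {
  withr::local_seed(77)
  for (rep in 1:10) {
    d <- sample(3:6, 1)
    U <- random_unitary(d)
    perm <- sample(d)
    ph <- exp(1i * stats::runif(d, 0, 2 * pi))
    U2 <- (U %*% diag(ph))[, perm]
    out <- align_gauge(U, U2)
    ## brute force: permutation maximizing total |overlap|
    O <- Conj(t(U)) %*% U2
    perms <- combinat_perms(d)
    scores <- vapply(perms, function(p) sum(Mod(O[cbind(seq_len(d), p)])), 1)
    best <- perms[[which.max(scores)]]
    expect_equal(attr(out, "permutation"), as.integer(best))
    expect_lt(max(Mod(out - U)), 1e-10)
  }
})

test_that("back transformation: identity, 45-degree rotation, exact norm preservation", {
  expect_equal(back_transform(diag(4) + 0i, c(0, 1, 0, 0) + 0i),
               c(0, 1, 0, 0) + 0i)
  th <- pi / 4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) + 0i
  b <- back_transform(R, c(1, 0) + 0i)
  expect_equal(Mod(b)^2, c(0.5, 0.5), tolerance = 1e-14)
  withr::local_seed(8)
  for (rep in 1:20) {
    d <- sample(2:10, 1)
    U <- random_unitary(d)
    cc <- random_coef(d)
    b <- back_transform(U, cc)
    expect_lt(abs(sum(Mod(b)^2) - 1), 1e-12)
    expect_true(all(Mod(b)^2 <= 1 + 1e-12))
  }
  expect_error(back_transform(diag(3) + 0i, c(1, 0) + 0i), "dimension")
  expect_error(back_transform(diag(2) + 0i, c(2, 0) + 0i), "normalized")
})

test_that("ensemble populations: pinning, averaging, and conservation", {
  m <- pair_model(soc_cm1 = 0)
  p <- dynamics_params(t_max_fs = 20, alpha = 0, initial_state = "S1", seed = 2)
  tr <- run_trajectory(m, list(coords = 0.1, momenta = 0), p)
  pop <- ensemble_populations(list(tr))
  s1 <- population_of(pop, "S1")
  expect_true(all(abs(s1$population - 1) < 1e-10))
  ## two synthetic trajectories with opposite pinned populations average to 0.5
  tr2 <- tr
  tr2$pop_diabatic <- tr$pop_diabatic[, c(2, 1, 3)]
  pop2 <- ensemble_populations(list(tr, tr2))
  expect_true(all(abs(population_of(pop2, "S0")$population - 0.5) < 1e-12))
  ## populations sum to 1 at every time on a coupled random model
  m3 <- random_smooth_model(19)
  s3 <- sample_wigner(m3$modes, 298, 3, seed = 4)
  p3 <- dynamics_params(t_max_fs = 30, alpha = 5, seed = 6)
  trs <- lapply(1:3, function(i) run_trajectory(m3, s3[i, ], p3))
  pop3 <- ensemble_populations(trs)
  tot <- dplyr::summarise(dplyr::group_by(pop3, t_fs),
                          s = sum(population))$s
  expect_true(all(abs(tot - 1) < 1e-8))
  expect_error(ensemble_populations(list()), "empty")
})

test_that("with SOC = 0 singlet and triplet totals are separately conserved", {
  m <- random_smooth_model(23)
  m$internal$soc_base_au[] <- 0 + 0i   # zero the couplings, keep the rest
  s <- sample_wigner(m$modes, 298, 2, seed = 11)
  p <- dynamics_params(t_max_fs = 50, alpha = 1, seed = 3)
  for (i in 1:2) {
    tr <- run_trajectory(m, s[i, ], p)
    stot <- rowSums(tr$pop_diabatic[, 1:2])
    expect_true(all(abs(stot - stot[1]) < 1e-8))
  }
})
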