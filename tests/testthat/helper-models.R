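# shared tiny model builders for the test suite

# single excited singlet on a harmonic surface, no couplings
harmonic_singlet_model <- function(freq_cm1 = 500, mass_amu = 10) {
  build_lvc_model(
    electronic_spec(2, 0, c(0, 3.0), oscillator_strengths = 0.5),
    mode_spec(freq_cm1, mass_amu),
    label = "harmonic singlet"
  )
}

# one singlet + one triplet, degenerate at the origin, constant SOC (cm^-1)
pair_model <- function(soc_cm1 = 100, gap_eV = 0, im_cm1 = 0) {
  build_lvc_model(
    electronic_spec(2, 1, c(0, 3.0, 3.0 + gap_eV)),
    mode_spec(500, 10),
    soc_spec(tibble::tibble(singlet = "S1", triplet = "T1",
                            component = 0L, re_cm1 = soc_cm1, im_cm1 = im_cm1)),
    label = "degenerate S/T pair"
  )
}

# random LVC model with smooth surfaces, seeded
random_smooth_model <- function(seed, n_singlets = 2, n_triplets = 2,
                                n_modes = 2) {
  withr::local_seed(seed)
  modes <- mode_spec(stats::runif(n_modes, 300, 1500),
                     stats::runif(n_modes, 2, 12))
  ns <- n_singlets + n_triplets
  e_s <- c(0, sort(stats::runif(n_singlets - 1, 2, 4)))
  e_t <- sort(stats::runif(n_triplets, 1.5, 4))
  grad <- matrix(stats::rnorm(ns * n_modes, 0, 0.3), ns, n_modes)
  grad[1, ] <- 0
  soc_tbl <- tidyr::expand_grid(
    singlet = paste0("S", seq_len(n_singlets - 1)),
    triplet = paste0("T", seq_len(n_triplets)),
    component = c(-1L, 0L, 1L)
  )
  soc_tbl$re_cm1 <- stats::rnorm(nrow(soc_tbl), 0, 50)
  soc_tbl$im_cm1 <- stats::rnorm(nrow(soc_tbl), 0, 50)
  build_lvc_model(
    electronic_spec(n_singlets, n_triplets, c(e_s, e_t), grad,
                    oscillator_strengths = stats::runif(n_singlets - 1, 0, 1)),
    modes, soc_spec(soc_tbl), label = paste("random smooth", seed)
  )
}

# random unitary matrix via QR of a complex Ginibre matrix
random_unitary <- function(d, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  Z <- matrix(complex(real = stats::rnorm(d * d), imaginary = stats::rnorm(d * d)), d)
  qr_z <- qr(Z)
  Q <- qr.Q(qr_z)
  R <- qr.R(qr_z)
  Q %*% diag(diag(R) / Mod(diag(R)), d)
}

# all permutations of 1..n (n <= 6), rows of a matrix
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1)
  out <- list()
  for (p in sub) for (pos in 0:(n - 1))
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

# random normalized complex coefficient vector
random_coef <- function(d, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  z <- complex(real = stats::rnorm(d), imaginary = stats::rnorm(d))
  z / sqrt(sum(Mod(z)^2))
}
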