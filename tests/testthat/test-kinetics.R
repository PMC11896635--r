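mk_series <- function(t, y) tibble::tibble(t_fs = t, population = y)

test_that("growth fit recovers noise-free parameters to 1e-6 relative", {
  t <- seq(0, 200, by = 0.5)
  y <- 0.8 * (1 - exp(-(t - 5) / 30))
  y[t < 5] <- 0  # physical curve: zero before onset
  ## fit on the post-onset window where the model form is exact
  f <- fit_growth(mk_series(t[t >= 5], y[t >= 5]))
  expect_equal(f$tau_fs, 30, tolerance = 1e-6)
  expect_equal(f$amplitude, 0.8, tolerance = 1e-6)
  expect_equal(f$shift_fs, 5, tolerance = 1e-4)
  expect_equal(f$model_form, "complementary_exponential_growth")
  expect_lt(f$residual_rms, 1e-8)
})

test_that("growth fit tau is robust under additive noise (median of repeats)", {
  t <- seq(0, 200, length.out = 400)
  clean <- 0.8 * (1 - exp(-t / 30))
  withr::local_seed(99)
  taus <- replicate(100, {
    y <- pmin(pmax(clean + rnorm(400, 0, 0.02), 0), 1)
    fit_growth(mk_series(t, y))$tau_fs
  })
  expect_lt(abs(stats::median(taus) - 30) / 30, 0.1)
})

test_that("decay fit: exact recovery, offset handled, degenerate inputs rejected", {
  t <- seq(0, 150, by = 0.5)
  f <- fit_decay(mk_series(t, exp(-t / 26.3)))
  expect_equal(f$tau_fs, 26.3, tolerance = 1e-6)
  expect_equal(f$amplitude, 1, tolerance = 1e-6)
  expect_equal(f$offset, 0, tolerance = 1e-6)
  ## constant baseline B = 0.2 does not bias tau
  withr::local_seed(7)
  taus <- replicate(100, {
    y <- pmin(pmax(0.2 + 0.7 * exp(-t / 40) + rnorm(length(t), 0, 0.02), 0), 1)
    fit_decay(mk_series(t, y))$tau_fs
  })
  expect_lt(abs(stats::median(taus) - 40) / 40, 0.1)
  expect_error(fit_decay(mk_series(1:3, c(1, 0.5, 0.2))), "10 time points")
  expect_error(fit_decay(mk_series(seq(0, 10, 0.5), rep(0, 21))), "constant")
  expect_error(fit_growth(mk_series(seq(0, 10, 0.5), rep(0, 21))), "constant")
})

test_that("extrapolation reproduces published-style lifetime triples", {
  ## triplet-population time constants
  ex_t <- extrapolate_to_unit_alpha(c(2, 3.5, 5), c(441.66, 28.44, 12.44))
  expect_equal(signif(ex_t$tau1_fs / 1000, 3), 6.06)
  ## S1 lifetimes
  ex_s1 <- extrapolate_to_unit_alpha(c(2, 3.5, 5), c(179.1, 26.3, 8.8))
  expect_equal(signif(ex_s1$tau1_fs / 1000, 3), 1.73)
  ## overall excited-singlet lifetimes
  ex_s <- extrapolate_to_unit_alpha(c(2, 3.5, 5), c(232.8, 27.9, 13.2))
  expect_lt(abs(ex_s$tau1_fs / 1000 - 1.93), 0.011)
  ## the printed triples are NOT consistent with a fixed -2 slope
  expect_lt(ex_t$slope, -3.5)
})

test_that("extrapolation recovers an exact alpha^-2 law to machine precision", {
  a <- c(1.5, 2, 3, 4.5)
  ex <- extrapolate_to_unit_alpha(a, 100 * a^-2)
  expect_equal(ex$tau1_fs, 100, tolerance = 1e-10)
  expect_equal(ex$slope, -2, tolerance = 1e-10)
  ## log-base invariance: same tau1 via natural-log regression
  fit_ln <- stats::lm(log(100 * a^-2) ~ log(a))
  expect_equal(ex$tau1_fs, exp(coef(fit_ln)[[1]]), tolerance = 1e-12)
  ## evaluating the fit back at each alpha reproduces the inputs
  pred <- 10^(ex$intercept + ex$slope * log10(a))
  expect_equal(pred, 100 * a^-2, tolerance = 1e-10)
  expect_error(extrapolate_to_unit_alpha(2, 10), "at least 2")
  expect_error(extrapolate_to_unit_alpha(c(2, 2), c(1, 2)), "duplicate")
  expect_error(extrapolate_to_unit_alpha(c(1, 2), c(1, 2)), "> 1")
})

test_that("rate conversion is exact and monotone", {
  expect_equal(rate_from_lifetime(1, "ns"), 1e9)
  expect_equal(rate_from_lifetime(6.06, "ps"), 1.650165e11, tolerance = 1e-6)
  taus <- c(1, 2, 5, 10)
  expect_true(all(diff(rate_from_lifetime(taus, "fs")) < 0))
  expect_error(rate_from_lifetime(-1, "fs"), "> 0")
})

test_that("Einstein emission rate matches the closed-form CODATA evaluation", {
  expect_equal(einstein_rate(2.56, 0), 0)
  ## functional form: quadratic in E_F, linear in f
  expect_equal(einstein_rate(2 * 2.56, 0.29) / einstein_rate(2.56, 0.29), 4,
               tolerance = 1e-12)
  expect_equal(einstein_rate(2.56, 0.58) / einstein_rate(2.56, 0.29), 2,
               tolerance = 1e-12)
  ## independent closed-form evaluation with SI constants
  e <- 1.602176634e-19; h <- 6.62607015e-34; eps0 <- 8.8541878128e-12
  me <- 9.1093837015e-31; cl <- 2.99792458e8
  k_ref <- 2 * pi * e^2 * (2.56 * e)^2 * 0.58 / (h^2 * eps0 * me * cl^3)
  expect_equal(einstein_rate(2.56, 0.58), k_ref, tolerance = 1e-12)
  expect_equal(signif(einstein_rate(2.56, 0.58), 3), 1.65e8)
})

test_that("triplet quantum yield: exact ratios and scale invariance", {
  expect_equal(triplet_quantum_yield(5, 0, 0), 1)
  expect_equal(triplet_quantum_yield(1, 1, 1), 1 / 3)
  expect_equal(triplet_quantum_yield(4, 1, 0), 0.8)
  withr::local_seed(14)
  for (rep in 1:10) {
    k <- runif(3, 0, 1e11)
    s <- runif(1, 1e-3, 1e3)
    expect_equal(triplet_quantum_yield(k[1], k[2], k[3]),
                 triplet_quantum_yield(s * k[1], s * k[2], s * k[3]),
                 tolerance = 1e-12)
  }
  expect_error(triplet_quantum_yield(0, 0, 0), "positive")
  expect_error(triplet_quantum_yield(-1, 1, 1), ">= 0")
})

test_that("rate sets combine rates and yield consistently", {
  rs <- rate_set(k_isc = 1.65e11, k_ic = 2.5e10, e_f_eV = 2.56, f = 0.58)
  expect_equal(rs$k_f, einstein_rate(2.56, 0.58))
  expect_equal(rs$phi_T,
               triplet_quantum_yield(1.65e11, 2.5e10, einstein_rate(2.56, 0.58)))
  expect_error(rate_set(1e11, 1e10), "either k_f")
})

test_that("tidy and glance methods expose fit summaries", {
  t <- seq(0, 100, by = 0.5)
  f <- fit_decay(mk_series(t, 0.1 + 0.9 * exp(-t / 20)))
  td <- tidy(f)
  expect_setequal(td$term, c("tau_fs", "amplitude", "shift_fs", "offset"))
  gl <- glance(f)
  expect_equal(gl$tau_fs, 20, tolerance = 1e-6)
  ex <- extrapolate_to_unit_alpha(c(2, 3.5, 5), c(441.66, 28.44, 12.44))
  expect_equal(glance(ex)$tau1_ps, 6.06, tolerance = 1e-3)
  expect_equal(nrow(tidy(ex)), 2L)
})
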