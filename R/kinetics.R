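#' Fit a complementary-exponential growth curve to a population series
#'
#' Least-squares fit of \eqn{p(t) = A (1 - e^{-(t - t_0)/\tau})} to the
#' summed population of a set of states (e.g. total triplet population after
#' photoexcitation), with amplitude A constrained to \[0, 1\] and onset
#' \eqn{t_0} free. Starting values come from the curve's 10%/90% rise times.
#'
#' @param series A `population_series` from [ensemble_populations()], or any
#'   tibble with `t_fs` and `population`.
#' @param states State selector passed to [population_of()] (ignored when
#'   `series` already has a single `population` column per time).
#' @return An object of class `decay_fit` with elements `tau_fs`,
#'   `amplitude`, `shift_fs`, `offset`, `model_form`, `residual_rms`,
#'   `n_points` and the underlying `fit`. [tidy()] and [glance()] methods
#'   are provided.
#' @export
fit_growth <- function(series, states = "triplets") {
  dat <- series_data(series, states)
  y <- dat$population; t <- dat$t_fs
  if (length(t) < 10L) stop("at least 10 time points are required")
  if (any(y < -1e-9) || any(y > 1 + 1e-9)) stop("populations must lie in [0, 1]")
  if (max(y) - min(y) < 1e-12)
    stop("constant series: growth time constant is unidentifiable")
  A0 <- min(max(max(y), 1e-3), 1)
  t10 <- t[which(y >= 0.1 * A0)[1]]
  t90 <- t[which(y >= 0.9 * A0)[1]]
  if (is.na(t90)) t90 <- max(t)
  tau0 <- max((t90 - t10) / 2.197, diff(range(t)) / 50)  # ln(0.9/0.1) = 2.197
  fit <- minpack.lm::nlsLM(
    population ~ A * (1 - exp(-(t_fs - t0) / tau)),
    data = dat,
    start = list(A = A0, t0 = max(t10 - tau0, min(t)), tau = tau0),
    lower = c(A = 0, t0 = -Inf, tau = 1e-6),
    upper = c(A = 1, t0 = Inf, tau = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- stats::coef(fit)
  new_decay_fit(tau_fs = cf[["tau"]], amplitude = cf[["A"]],
                shift_fs = cf[["t0"]], offset = 0,
                model_form = "complementary_exponential_growth",
                fit = fit, n_points = length(t))
}

#' Fit a scaled and shifted exponential decay to a population series
#'
#' Least-squares fit of \eqn{p(t) = B + A e^{-(t - t_0)/\tau}} to the summed
#' population of a set of states (e.g. the S1 population). The time shift
#' \eqn{t_0} is fixed at the first time point of the series — for a pure
#' decay it is redundant with the amplitude (A absorbs \eqn{e^{t_0/\tau}})
#' and fitting both would be unidentifiable. The baseline B >= 0 absorbs any
#' population plateau.
#'
#' @inheritParams fit_growth
#' @return A `decay_fit` (see [fit_growth()]), `model_form`
#'   `"exponential_decay"`.
#' @export
fit_decay <- function(series, states = "S1") {
  dat <- series_data(series, states)
  y <- dat$population; t <- dat$t_fs
  if (length(t) < 10L) stop("at least 10 time points are required")
  if (any(y < -1e-9) || any(y > 1 + 1e-9)) stop("populations must lie in [0, 1]")
  if (max(y) - min(y) < 1e-12)
    stop("constant series: decay lifetime is unidentifiable")
  t0 <- min(t)
  B0 <- max(min(y), 0)
  A0 <- min(max(y[which.min(t)] - B0, 1e-3), 1)
  drop_frac <- (y - B0) / A0
  t37 <- t[which(drop_frac <= exp(-1))[1]]
  tau0 <- if (is.na(t37)) diff(range(t)) else max(t37 - t0, diff(range(t)) / 100)
  fit <- minpack.lm::nlsLM(
    population ~ B + A * exp(-(t_fs - t0) / tau),
    data = cbind(dat, t0 = t0),
    start = list(A = A0, B = B0, tau = tau0),
    lower = c(A = 0, B = 0, tau = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- stats::coef(fit)
  new_decay_fit(tau_fs = cf[["tau"]], amplitude = cf[["A"]],
                shift_fs = t0, offset = cf[["B"]],
                model_form = "exponential_decay",
                fit = fit, n_points = length(t))
}

series_data <- function(series, states) {
  if (inherits(series, "population_series")) population_of(series, states)
  else tibble::as_tibble(series)[, c("t_fs", "population")]
}

new_decay_fit <- function(tau_fs, amplitude, shift_fs, offset, model_form,
                          fit, n_points) {
  if (tau_fs <= 0) stop("fitted tau is non-positive: fit did not converge sensibly")
  structure(list(tau_fs = tau_fs, amplitude = amplitude, shift_fs = shift_fs,
                 offset = offset, model_form = model_form,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 n_points = n_points, fit = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> ", x$model_form, ": tau = ", signif(x$tau_fs, 4),
      " fs (A = ", signif(x$amplitude, 3),
      ", residual rms = ", signif(x$residual_rms, 2), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("tau_fs", "amplitude", "shift_fs", "offset"),
    estimate = c(x$tau_fs, x$amplitude, x$shift_fs, x$offset)
  )
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(tau_fs = x$tau_fs, model_form = x$model_form,
                 residual_rms = x$residual_rms, n_points = x$n_points)
}

#' Extrapolate fitted lifetimes to the unscaled coupling
#'
#' Accelerated nonadiabatic dynamics scales the spin-orbit coupling by a
#' factor alpha > 1; golden-rule rates then scale as alpha^2 and lifetimes
#' as \eqn{\tau_\alpha = \tau_1 \alpha^{-2}}. This function fits an
#' unweighted straight line to \eqn{\log_{10}\tau} vs
#' \eqn{\log_{10}\alpha} with a FREE slope and evaluates it at alpha = 1.
#' The slope is reported so its deviation from the theoretical -2 can be
#' inspected; lifetimes obtained from finite ensembles routinely deviate
#' from the ideal law, and the free-slope fit is what makes extrapolated
#' lifetimes reproducible from printed time-constant triples.
#'
#' @param alphas Numeric vector of scaling factors (> 1, distinct), length
#'   >= 2.
#' @param taus_fs Fitted lifetimes (fs), > 0, same length.
#' @return Object of class `alpha_extrapolation`: `tau1_fs`, `slope`,
#'   `intercept` (log10 fs), `alphas`, `taus_fs`, `fit`.
#' @examples
#' extrapolate_to_unit_alpha(c(2, 3.5, 5), c(441.66, 28.44, 12.44))$tau1_fs
#' @export
extrapolate_to_unit_alpha <- function(alphas, taus_fs) {
  if (length(alphas) < 2L) stop("at least 2 (alpha, tau) points are required")
  if (length(alphas) != length(taus_fs)) stop("alphas and taus_fs lengths differ")
  if (anyDuplicated(alphas)) stop("duplicate alphas")
  if (any(alphas <= 1)) stop("all alphas must be > 1")
  if (any(taus_fs <= 0)) stop("all lifetimes must be > 0")
  dat <- data.frame(la = log10(alphas), lt = log10(taus_fs))
  fit <- stats::lm(lt ~ la, data = dat)
  cf <- stats::coef(fit)
  structure(list(tau1_fs = 10^cf[[1]], slope = cf[[2]], intercept = cf[[1]],
                 alphas = alphas, taus_fs = taus_fs, fit = fit),
            class = "alpha_extrapolation")
}

#' @export
print.alpha_extrapolation <- function(x, ...) {
  cat("<alpha_extrapolation> tau(alpha = 1) = ", signif(x$tau1_fs / 1000, 3),
      " ps (slope ", signif(x$slope, 3), ", theoretical -2)\n", sep = "")
  invisible(x)
}

#' @export
tidy.alpha_extrapolation <- function(x, ...) {
  tibble::tibble(term = c("intercept_log10fs", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.alpha_extrapolation <- function(x, ...) {
  tibble::tibble(tau1_fs = x$tau1_fs, tau1_ps = x$tau1_fs / 1000,
                 slope = x$slope, n = length(x$alphas),
                 r_squared = summary(x$fit)$r.squared)
}

#' Rate constant from a lifetime
#'
#' k = 1 / tau, converted to s^-1.
#'
#' @param tau Lifetime, > 0.
#' @param unit Unit of `tau`: one of "fs", "ps", "ns", "s".
#' @return Rate in s^-1.
#' @examples
#' rate_from_lifetime(1, "ns")  # 1e9
#' @export
rate_from_lifetime <- function(tau, unit = c("fs", "ps", "ns", "s")) {
  unit <- match.arg(unit)
  if (any(tau <= 0)) stop("tau must be > 0")
  to_s <- c(fs = 1e-15, ps = 1e-12, ns = 1e-9, s = 1)[[unit]]
  1 / (tau * to_s)
}

#' Einstein spontaneous-emission (fluorescence) rate
#'
#' \deqn{k_F = \frac{2\pi e^2 E_F^2}{h^2 \varepsilon_0 m c^3} f}
#' with the fluorescence emission energy \eqn{E_F} and oscillator strength
#' f; constants are CODATA 2018 SI values.
#'
#' @param e_f_eV Emission energy (eV), > 0.
#' @param f Oscillator strength, >= 0.
#' @return Rate in s^-1.
#' @examples
#' einstein_rate(2.56, 0.58)  # ~1.65e8 s^-1
#' @export
einstein_rate <- function(e_f_eV, f) {
  if (e_f_eV <= 0) stop("emission energy must be > 0")
  if (f < 0) stop("oscillator strength must be >= 0")
  cst <- physical_constants()
  E_J <- e_f_eV * cst$e
  2 * pi * cst$e^2 * E_J^2 * f / (cst$h^2 * cst$eps0 * cst$m_e * cst$c^3)
}

#' Bundle photophysical rates into a rate set with its quantum yield
#'
#' Collects the ISC, IC and fluorescence rate constants (s^-1) together
#' with the emission energy and oscillator strength that produced k_F, and
#' computes the triplet quantum yield. When `k_f` is omitted it is computed
#' from `e_f_eV` and `f` via [einstein_rate()].
#'
#' @param k_isc,k_ic Rates in s^-1, >= 0.
#' @param k_f Fluorescence rate in s^-1; default `einstein_rate(e_f_eV, f)`.
#' @param e_f_eV,f Optional emission energy (eV) and oscillator strength.
#' @return A list of class `rate_set` with `k_isc`, `k_ic`, `k_f`,
#'   `phi_T`, `e_f_eV`, `f`.
#' @export
rate_set <- function(k_isc, k_ic, k_f = NULL, e_f_eV = NA, f = NA) {
  if (is.null(k_f)) {
    if (is.na(e_f_eV) || is.na(f))
      stop("either k_f or both e_f_eV and f must be given")
    k_f <- einstein_rate(e_f_eV, f)
  }
  structure(list(k_isc = k_isc, k_ic = k_ic, k_f = k_f,
                 phi_T = triplet_quantum_yield(k_isc, k_ic, k_f),
                 e_f_eV = e_f_eV, f = f),
            class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set> k_ISC = ", signif(x$k_isc, 4), ", k_IC = ", signif(x$k_ic, 4),
      ", k_F = ", signif(x$k_f, 4), " s^-1; Phi_T = ", signif(x$phi_T, 3),
      "\n", sep = "")
  invisible(x)
}

#' Triplet quantum yield
#'
#' \eqn{\Phi_T = k_{ISC} / (k_{ISC} + k_{IC} + k_F)}: the fraction of
#' excited-state decay flux passing through intersystem crossing. Invariant
#' under rescaling all three rates by a common factor.
#'
#' @param k_isc,k_ic,k_f Non-negative rates in any one common unit; their
#'   sum must be positive.
#' @return Yield in \[0, 1\].
#' @examples
#' triplet_quantum_yield(4, 1, 0)  # 0.8
#' @export
triplet_quantum_yield <- function(k_isc, k_ic, k_f) {
  if (any(c(k_isc, k_ic, k_f) < 0)) stop("rates must be >= 0")
  tot <- k_isc + k_ic + k_f
  if (tot <= 0) stop("at least one rate must be positive")
  k_isc / tot
}
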