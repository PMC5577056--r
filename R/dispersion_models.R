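# Two-state chemical-exchange forward models for CPMG relaxation dispersion.
#
# Convention used throughout: nu_cpmg = 1/(2*tau_cp), tau_cp the delay between
# consecutive 180-degree pulses.  The Bloch-McConnell propagator
# (bloch_mcconnell_r2eff) is the single source of truth for prefactors; the
# closed forms below reproduce it (see the package tests and vignette).

#' Gyromagnetic frequency ratio of 15N relative to 1H
#'
#' Used to convert ppm-level chemical-shift differences to rad/s at a given
#' proton Larmor frequency.
#' @export
NITROGEN15_RATIO <- 0.10136767

#' Static-field context for a dispersion measurement
#'
#' @param spectrometer_frequency Proton Larmor frequency in MHz (e.g. 600.13).
#' @param nucleus_ratio Gyromagnetic ratio of the observed nucleus relative to
#'   the proton; defaults to the 15N value [NITROGEN15_RATIO].
#' @return An object of class `field_context`.
#' @examples
#' field_context(600.13)
#' @export
field_context <- function(spectrometer_frequency,
                          nucleus_ratio = NITROGEN15_RATIO) {
  stopifnot(is.numeric(spectrometer_frequency),
            length(spectrometer_frequency) == 1L,
            is.finite(spectrometer_frequency))
  if (spectrometer_frequency <= 0)
    stop("spectrometer_frequency must be > 0")
  if (!is.numeric(nucleus_ratio) || nucleus_ratio <= 0 || nucleus_ratio > 1)
    stop("nucleus_ratio must lie in (0, 1]")
  structure(list(spectrometer_frequency = spectrometer_frequency,
                 nucleus_ratio = nucleus_ratio),
            class = "field_context")
}

#' @export
print.field_context <- function(x, ...) {
  cat(sprintf("<field_context> %.2f MHz (1H); observed nucleus %.2f MHz\n",
              x$spectrometer_frequency,
              x$spectrometer_frequency * x$nucleus_ratio))
  invisible(x)
}

# ppm -> rad/s for the observed nucleus at this field.
# 1 ppm corresponds to (f_MHz * ratio) Hz.
ppm_to_rad <- function(ppm, field) {
  ppm * 2 * pi * field$spectrometer_frequency * field$nucleus_ratio
}

#' Two-state exchange parameters
#'
#' Container for the parameters of a two-state (major <-> minor) exchange
#' process at one residue.  The slow/intermediate (Carver-Richards) model uses
#' `p_minor` and `delta_omega_ppm`; the fast-exchange (Luz-Meiboom) model uses
#' the amplitude `phi_ppm2` = p_major * p_minor * delta_delta^2, the only
#' shift/population combination identifiable in fast exchange.
#'
#' @param r2_0 Intrinsic (exchange-free, population-average) transverse
#'   relaxation rate, 1/s.
#' @param k_ex Exchange rate (sum of forward and reverse rate constants), 1/s.
#' @param p_minor Minor-state population, in `[0, 0.5]`.
#' @param delta_omega_ppm Chemical-shift difference between the states, ppm.
#' @param phi_ppm2 Fast-exchange amplitude, ppm^2.
#' @return An object of class `exchange_params`.
#' @examples
#' exchange_params(r2_0 = 15, k_ex = 840, p_minor = 0.03, delta_omega_ppm = 1.2)
#' exchange_params(r2_0 = 15, k_ex = 2033, phi_ppm2 = 0.05)
#' @export
exchange_params <- function(r2_0, k_ex, p_minor = NULL,
                            delta_omega_ppm = NULL, phi_ppm2 = NULL) {
  stopifnot(is.numeric(r2_0), is.numeric(k_ex))
  if (r2_0 < 0) stop("r2_0 must be >= 0")
  if (k_ex <= 0) stop("k_ex must be > 0")
  if (!is.null(p_minor) &&
      (p_minor < 0 || p_minor > 0.5)) stop("p_minor must lie in [0, 0.5]")
  if (!is.null(phi_ppm2) && phi_ppm2 < 0) stop("phi_ppm2 must be >= 0")
  structure(list(r2_0 = r2_0, k_ex = k_ex, p_minor = p_minor,
                 delta_omega_ppm = delta_omega_ppm, phi_ppm2 = phi_ppm2),
            class = "exchange_params")
}

#' CPMG frequency grid with constant-time relaxation period
#'
#' @param nu_cpmg CPMG field strengths in Hz (`1/(2*tau_cp)`), strictly
#'   increasing and positive.
#' @param relaxation_period Constant-time CPMG relaxation period in seconds.
#' @return An object of class `cpmg_grid`.
#' @export
cpmg_grid <- function(nu_cpmg, relaxation_period) {
  stopifnot(is.numeric(nu_cpmg), length(nu_cpmg) >= 1L)
  if (any(nu_cpmg <= 0)) stop("all nu_cpmg must be > 0")
  if (is.unsorted(nu_cpmg, strictly = TRUE))
    stop("nu_cpmg must be strictly increasing")
  if (!is.numeric(relaxation_period) || relaxation_period <= 0)
    stop("relaxation_period must be > 0")
  structure(list(nu_cpmg = nu_cpmg, relaxation_period = relaxation_period),
            class = "cpmg_grid")
}

#' Effective R2 from constant-time CPMG peak intensities
#'
#' Converts a peak intensity measured with a CPMG relaxation period of length
#' `relaxation_period` and a reference intensity measured without the period
#' into an effective transverse relaxation rate, `-log(I/I0)/T`.
#'
#' @param intensity Peak intensity with the relaxation period (vectorised).
#' @param reference_intensity Reference intensity without the period.
#' @param relaxation_period Constant-time relaxation period, seconds.
#' @return Effective R2 in 1/s.
#' @examples
#' r2eff_from_intensity(0.5, 1, 0.02)  # log(2)/0.02 = 34.66 1/s
#' @export
r2eff_from_intensity <- function(intensity, reference_intensity,
                                 relaxation_period) {
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("intensity must be positive and finite")
  if (any(!is.finite(reference_intensity)) || any(reference_intensity <= 0))
    stop("reference_intensity must be positive and finite")
  if (relaxation_period <= 0) stop("relaxation_period must be > 0")
  -log(intensity / reference_intensity) / relaxation_period
}

#' Luz-Meiboom fast-exchange dispersion model
#'
#' Effective R2 for two-state exchange in the fast regime:
#' `R2eff = R2_0 + (Phi/k_ex) * (1 - (4 nu/k_ex) * tanh(k_ex/(4 nu)))`
#' with `Phi` converted from ppm^2 to rad^2/s^2 at the given field.
#'
#' @param nu_cpmg CPMG field strength(s) in Hz.
#' @param params [exchange_params] with `phi_ppm2` set.
#' @param field [field_context].
#' @return Effective R2 in 1/s, same length as `nu_cpmg`.
#' @export
luz_meiboom_r2eff <- function(nu_cpmg, params, field) {
  if (is.null(params$phi_ppm2)) stop("params$phi_ppm2 must be set")
  if (params$phi_ppm2 < 0) stop("phi_ppm2 must be >= 0")
  if (params$k_ex <= 0) stop("k_ex must be > 0")
  omega1 <- ppm_to_rad(1, field)
  phi_rad <- params$phi_ppm2 * omega1^2
  kex <- params$k_ex
  params$r2_0 + (phi_rad / kex) *
    (1 - (4 * nu_cpmg / kex) * tanh(kex / (4 * nu_cpmg)))
}

# warning counter for arccosh-domain clamps (floating error can push the
# arccosh argument slightly below 1); see acosh_clamp_count().
.fluctedit_state <- new.env(parent = emptyenv())
.fluctedit_state$acosh_clamps <- 0L

#' Number of arccosh-domain clamps performed so far
#'
#' [carver_richards_r2eff()] clamps arccosh arguments that fall below 1 by
#' floating rounding instead of raising an error; each clamp increments this
#' session counter.
#' @param reset If `TRUE`, reset the counter to zero after reading.
#' @return Integer count.
#' @export
acosh_clamp_count <- function(reset = FALSE) {
  n <- .fluctedit_state$acosh_clamps
  if (reset) .fluctedit_state$acosh_clamps <- 0L
  n
}

#' Carver-Richards two-state dispersion model
#'
#' Closed-form effective R2 for two-state exchange with equal intrinsic rates,
#' valid through the slow and intermediate regimes:
#' `R2eff = R2_0 + k_ex/2 - nu * arccosh(D+ cosh(eta+) - D- cos(eta-))` with
#' `Psi = k_ex^2 - dw^2`, `zeta^2 = 4 dw^2 k_ex^2 (p_major - p_minor)^2`,
#' `D+- = (+-1 + (Psi + 2 dw^2)/sqrt(Psi^2 + zeta^2))/2` and
#' `eta+- = sqrt(+-Psi + sqrt(Psi^2 + zeta^2)) / (2 sqrt(2) nu)`,
#' where `dw` is the shift difference in rad/s at the given field.
#'
#' @inheritParams luz_meiboom_r2eff
#' @param params [exchange_params] with `p_minor` and `delta_omega_ppm` set.
#' @return Effective R2 in 1/s.
#' @export
carver_richards_r2eff <- function(nu_cpmg, params, field) {
  if (is.null(params$p_minor) || is.null(params$delta_omega_ppm))
    stop("params$p_minor and params$delta_omega_ppm must be set")
  pb <- params$p_minor
  pa <- 1 - pb
  kex <- params$k_ex
  dw <- ppm_to_rad(params$delta_omega_ppm, field)
  psi <- kex^2 - dw^2
  zeta2 <- 4 * dw^2 * kex^2 * (pa - pb)^2
  rt <- sqrt(psi^2 + zeta2)
  d_plus <- 0.5 * (1 + (psi + 2 * dw^2) / rt)
  d_minus <- 0.5 * (-1 + (psi + 2 * dw^2) / rt)
  eta_plus <- sqrt(pmax(psi + rt, 0)) / (2 * sqrt(2) * nu_cpmg)
  eta_minus <- sqrt(pmax(-psi + rt, 0)) / (2 * sqrt(2) * nu_cpmg)
  big <- eta_plus > 350  # cosh would overflow; use acosh(x) ~ log(2x)
  arg <- d_plus * cosh(pmin(eta_plus, 350)) - d_minus * cos(eta_minus)
  below <- !big & arg < 1
  if (any(below)) {
    .fluctedit_state$acosh_clamps <- .fluctedit_state$acosh_clamps +
      sum(below)
    # tolerate only rounding-level violations silently-ish; larger ones are
    # still clamped but flagged loudly
    if (any(arg[below] < 1 - 1e-8))
      warning("arccosh argument < 1 beyond rounding tolerance; clamped")
    arg[below] <- 1
  }
  ac <- acosh(pmax(arg, 1))
  ac[big] <- eta_plus[big] + log(d_plus)
  out <- params$r2_0 + kex / 2 - nu_cpmg * ac
  if (any(!is.finite(out))) stop("Carver-Richards evaluation produced NaN/Inf")
  out
}

# closed-form exponential of a 2x2 complex matrix
expm_2x2 <- function(m) {
  mu <- (m[1, 1] + m[2, 2]) / 2
  delta <- sqrt((m[1, 1] - m[2, 2])^2 / 4 + m[1, 2] * m[2, 1] + 0i)
  ch <- cosh(delta)
  sh <- if (Mod(delta) < 1e-8) 1 + delta^2 / 6 else sinh(delta) / delta
  exp(mu) * (ch * diag(2) + sh * (m - mu * diag(2)))
}

#' Numerical Bloch-McConnell CPMG propagator (oracle)
#'
#' Propagates the two-state transverse magnetization through an explicit
#' constant-time CPMG echo train (free precession/exchange evolution
#' alternating with ideal, instantaneous 180-degree refocusing pulses) and
#' returns the effective relaxation rate of the major-state component,
#' `-log(|M_A(T)|/|M_A(0)|)/T`.  Magnetization starts at the equilibrium
#' populations.  This routine is the ground truth against which the two
#' closed forms are validated; note that for short relaxation periods its
#' intensity-based rate differs from the asymptotic closed-form rate by a
#' projection offset of order 1/T (see the vignette).
#'
#' The echo count is `2 * floor(relaxation_period * nu_cpmg)` (an even number
#' of `tau_cp`-long echo units); if the relaxation period is not an exact
#' multiple of the echo block, the count is rounded down and a warning issued.
#'
#' @inheritParams luz_meiboom_r2eff
#' @param params [exchange_params] with `p_minor` and `delta_omega_ppm` set.
#' @param relaxation_period Constant-time CPMG period in seconds.
#' @return Effective R2 in 1/s.
#' @export
bloch_mcconnell_r2eff <- function(nu_cpmg, params, field,
                                  relaxation_period = 0.04) {
  if (is.null(params$p_minor) || is.null(params$delta_omega_ppm))
    stop("params$p_minor and params$delta_omega_ppm must be set")
  pb <- params$p_minor
  pa <- 1 - pb
  kex <- params$k_ex
  dw <- ppm_to_rad(params$delta_omega_ppm, field)
  kab <- pb * kex  # major -> minor
  kba <- pa * kex  # minor -> major
  r2 <- params$r2_0
  vapply(nu_cpmg, function(nu) {
    tau_cp <- 1 / (2 * nu)
    n_echo_exact <- relaxation_period * nu  # = T / (2 * tau_cp)
    n_echo <- floor(n_echo_exact + 1e-9)
    if (n_echo < 1L)
      stop("relaxation_period too short for nu_cpmg = ", nu, " Hz")
    if (abs(n_echo_exact - round(n_echo_exact)) > 1e-9)
      warning(sprintf(
        "relaxation period is not a multiple of the echo block at %g Hz; %d echo pairs used",
        nu, n_echo))
    t_eff <- 2 * n_echo * tau_cp
    ll <- matrix(c(-r2 - kab, kab,
                   kba, -r2 - kba - 1i * dw), 2, 2)
    prop <- expm_2x2(ll * (tau_cp / 2))
    m <- c(pa + 0i, pb + 0i)
    # a pair of echoes (delay-180-delay twice) is a linear map U on M, the
    # pulse conjugations cancelling; n_echo pairs are applied as U^n via the
    # eigendecomposition, with an explicit echo loop as fallback
    u <- prop %*% Conj(prop) %*% Conj(prop) %*% prop
    ev <- tryCatch(eigen(u), error = function(e) NULL)
    detv <- if (is.null(ev)) 0 else
      ev$vectors[1, 1] * ev$vectors[2, 2] - ev$vectors[1, 2] * ev$vectors[2, 1]
    if (!is.null(ev) && Mod(detv) > 1e-12) {
      m <- ev$vectors %*% (ev$values^n_echo *
                             solve(ev$vectors, m))
    } else {
      for (i in seq_len(2L * n_echo)) m <- prop %*% Conj(prop %*% m)
    }
    -log(Mod(m[1]) / pa) / t_eff
  }, numeric(1))
}

#' Dispersion amplitude R_ex
#'
#' The exchange contribution to transverse relaxation: effective R2 in the
#' limit of zero pulsing frequency minus the limit of infinite pulsing
#' frequency.  For the fast-exchange model this is exactly `Phi_rad / k_ex`;
#' for Carver-Richards the analytic zero-frequency limit
#' `k_ex/2 - sqrt(Psi + sqrt(Psi^2 + zeta^2)) / (2 sqrt(2))` is used
#' (the infinite-frequency limit is `R2_0` for both models).
#'
#' @param params [exchange_params].
#' @param field [field_context].
#' @param model `"luz_meiboom"` or `"carver_richards"`.
#' @return R_ex in 1/s (non-negative).
#' @export
rex_amplitude <- function(params, field,
                          model = c("luz_meiboom", "carver_richards")) {
  model <- match.arg(model)
  if (model == "luz_meiboom") {
    if (is.null(params$phi_ppm2)) stop("params$phi_ppm2 must be set")
    phi_rad <- params$phi_ppm2 * ppm_to_rad(1, field)^2
    return(phi_rad / params$k_ex)
  }
  if (is.null(params$p_minor) || is.null(params$delta_omega_ppm))
    stop("params$p_minor and params$delta_omega_ppm must be set")
  pb <- params$p_minor
  kex <- params$k_ex
  dw <- ppm_to_rad(params$delta_omega_ppm, field)
  psi <- kex^2 - dw^2
  zeta2 <- 4 * dw^2 * kex^2 * (1 - 2 * pb)^2
  rt <- sqrt(psi^2 + zeta2)
  rex <- kex / 2 - sqrt(pmax(psi + rt, 0)) / (2 * sqrt(2))
  max(rex, 0)
}
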