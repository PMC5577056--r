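# Binding thermodynamics: Gibbs/entropy decomposition from K_A and dH,
# error-weighted heat-capacity regression, the one-site ITC forward model and
# its least-squares inversion, and baseline-corrected DSC enthalpy
# integration.  Canonical units: K, kJ/mol, M; kcal accepted on input with
# the declared 4.184 conversion.

#' Gas constant, J/(mol K)
#' @export
GAS_CONSTANT <- 8.314

#' kJ per kcal
#' @export
KCAL_TO_KJ <- 4.184

#' Gibbs energy from an association constant
#'
#' `dG = -R T ln(K_A) / 1000` in kJ/mol.
#'
#' @param ka Association constant in 1/M (> 0).
#' @param temperature Temperature in K.
#' @return Binding free energy in kJ/mol.
#' @examples
#' gibbs_from_ka(2.0e9, 293)  # -52.17 kJ/mol
#' @export
gibbs_from_ka <- function(ka, temperature) {
  if (any(ka <= 0)) stop("ka must be > 0")
  if (any(temperature <= 0)) stop("temperature must be > 0")
  -GAS_CONSTANT * temperature * log(ka) / 1000
}

#' Entropic term of binding
#'
#' `T dS = dH - dG` (kJ/mol).
#'
#' @param delta_h Binding enthalpy, kJ/mol.
#' @param delta_g Binding free energy, kJ/mol.
#' @return `T dS` in kJ/mol.
#' @examples
#' entropy_term(-99.50, gibbs_from_ka(2.0e9, 293))  # -47.33
#' @export
entropy_term <- function(delta_h, delta_g) delta_h - delta_g

#' Error-weighted heat-capacity change
#'
#' Weighted least-squares slope of binding enthalpy versus temperature with
#' weights `1/sigma^2`; the slope is the binding heat-capacity change dCp.
#' The standard error comes from the weighted normal equations (chi-square
#' errors, no residual-variance rescaling).
#'
#' @param temperatures Temperatures in K (>= 3 distinct values).
#' @param delta_h Enthalpies in kJ/mol.
#' @param sigma Enthalpy errors in kJ/mol (> 0).
#' @return List with `delta_cp` (slope, kJ/mol/K), `delta_cp_se`,
#'   `intercept`, and the fitted values.
#' @examples
#' delta_cp_weighted(c(293, 298, 303), c(-99.50, -113.40, -130.29),
#'                   c(0.25, 0.36, 1.45))$delta_cp  # -2.85
#' @export
delta_cp_weighted <- function(temperatures, delta_h, sigma) {
  n <- length(temperatures)
  stopifnot(length(delta_h) == n, length(sigma) == n)
  if (n < 3) stop("need >= 3 points")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (length(unique(temperatures)) < 2)
    stop("invalid design: degenerate temperatures")
  w <- 1 / sigma^2
  x <- cbind(1, temperatures)
  xtw <- t(x * w)
  covm <- solve(xtw %*% x)
  beta <- unname(drop(covm %*% (xtw %*% delta_h)))
  list(delta_cp = beta[2], delta_cp_se = sqrt(covm[2, 2]),
       intercept = beta[1], fitted = unname(drop(x %*% beta)))
}

#' Describe an ITC titration
#'
#' Geometry and (optionally) observed heats of an isothermal titration:
#' a macromolecule solution in the cell titrated with `length(injection_volumes)`
#' injections from the syringe.
#'
#' @param cell_concentration Macromolecule concentration in the cell, M.
#' @param syringe_concentration Titrant concentration in the syringe, M.
#' @param cell_volume Cell volume in L.
#' @param injection_volumes Injection volumes in L (>= 5 injections).
#' @param temperature Temperature in K.
#' @param heats Optional observed heats per injection.
#' @param heat_unit Unit of `heats`: `"J"` (canonical) or `"ucal"`
#'   (converted on input).
#' @return An object of class `itc_experiment` (heats stored in J).
#' @export
itc_experiment <- function(cell_concentration, syringe_concentration,
                           cell_volume, injection_volumes, temperature,
                           heats = NULL, heat_unit = c("J", "ucal")) {
  heat_unit <- match.arg(heat_unit)
  stopifnot(cell_concentration > 0, syringe_concentration > 0,
            cell_volume > 0, all(injection_volumes > 0), temperature > 0)
  if (length(injection_volumes) < 5) stop("need >= 5 injections")
  if (!is.null(heats)) {
    stopifnot(length(heats) == length(injection_volumes))
    if (heat_unit == "ucal") heats <- heats * KCAL_TO_KJ * 1e-3  # ucal -> J
  }
  structure(list(cell_concentration = cell_concentration,
                 syringe_concentration = syringe_concentration,
                 cell_volume = cell_volume,
                 injection_volumes = injection_volumes,
                 temperature = temperature, heats = heats),
            class = "itc_experiment")
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf(
    "<itc_experiment> %d x %.1f ul of %.3g M into %.3g M (cell %.2g ml, %.1f K)%s\n",
    length(x$injection_volumes), mean(x$injection_volumes) * 1e6,
    x$syringe_concentration, x$cell_concentration, x$cell_volume * 1e3,
    x$temperature, if (is.null(x$heats)) "" else "; heats present"))
  invisible(x)
}

#' One-site ITC forward model
#'
#' Expected heat per injection for 1:1 binding with `n` equivalent sites on
#' the cell macromolecule.  Volume displacement is handled by perfect-mixing
#' bookkeeping: each injection of volume `v` dilutes the cell contents by
#' `(1 - v/V0)` and adds `v/V0` of syringe titrant.  After each injection the
#' bound-complex concentration solves the 1:1 mass-balance quadratic
#' (evaluated in its cancellation-free form), and the measured heat is
#' `dH * V0 * (complex_i - complex_{i-1} * (1 - v/V0))`.
#'
#' @param ka Association constant, 1/M.
#' @param delta_h Binding enthalpy, kJ/mol.
#' @param n Stoichiometry (sites per macromolecule).
#' @param experiment An [itc_experiment()] (geometry; heats ignored).
#' @return List with `heats` (J per injection), and the per-injection totals
#'   and equilibrium concentrations (`macromolecule_total`, `titrant_total`,
#'   `complex`, `free_sites`, `free_titrant`, all M).
#' @export
one_site_itc_heats <- function(ka, delta_h, n = 1, experiment) {
  stopifnot(inherits(experiment, "itc_experiment"), ka > 0, n > 0)
  v0 <- experiment$cell_volume
  vols <- experiment$injection_volumes
  ni <- length(vols)
  mt <- xt <- cx <- numeric(ni)
  m_prev <- experiment$cell_concentration
  x_prev <- 0
  c_prev <- 0
  heats <- numeric(ni)
  for (i in seq_len(ni)) {
    dil <- 1 - vols[i] / v0
    mt[i] <- m_prev * dil
    xt[i] <- x_prev * dil + experiment$syringe_concentration * vols[i] / v0
    st <- n * mt[i]
    b <- st + xt[i] + 1 / ka
    disc <- b^2 - 4 * st * xt[i]
    cx[i] <- 2 * st * xt[i] / (b + sqrt(max(disc, 0)))
    heats[i] <- delta_h * 1000 * v0 * (cx[i] - c_prev * dil)
    m_prev <- mt[i]; x_prev <- xt[i]; c_prev <- cx[i]
  }
  list(heats = heats, macromolecule_total = mt, titrant_total = xt,
       complex = cx, free_sites = n * mt - cx, free_titrant = xt - cx)
}

#' Fit the one-site binding model to an ITC isotherm
#'
#' Least squares over `(K_A, dH, n)` with multi-start on `log10 K_A`;
#' parameter errors from the covariance at the optimum (scaled by the
#' residual variance).  Injection order is meaningful and preserved.
#'
#' @param experiment An [itc_experiment()] carrying observed `heats`.
#' @param log10_ka_starts Start values for `log10(K_A)`.
#' @param dilution_heat Fit a constant per-injection heat-of-dilution offset
#'   (off by default).
#' @return An object of class `itc_fit` with elements `ka`, `delta_h`, `n`
#'   (+ `_se` errors), `chi2`, `dof`, and methods `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' ex <- gen_itc_experiment(itc_scenario(noise_sd = 0, seed = 1))
#' fit <- fit_itc(ex$experiment)
#' coef(fit)[c("ka", "delta_h", "n")]
#' @export
fit_itc <- function(experiment, log10_ka_starts = 4:12,
                    dilution_heat = FALSE) {
  stopifnot(inherits(experiment, "itc_experiment"))
  obs <- experiment$heats
  if (is.null(obs)) stop("experiment carries no observed heats")
  if (length(obs) < 5) stop("need >= 5 informative injections")
  scale0 <- stats::median(abs(obs))
  if (scale0 == 0) scale0 <- 1
  resid_fn <- function(p) {
    mdl <- one_site_itc_heats(10^p[1], p[2], p[3], experiment)$heats
    if (dilution_heat) mdl <- mdl + p[4]
    (obs - mdl) / scale0
  }
  dh0 <- sum(obs) / 1000 /
    (min(experiment$cell_concentration * experiment$cell_volume,
         experiment$syringe_concentration * sum(experiment$injection_volumes)))
  lower <- c(1, -1e5, 0.05, if (dilution_heat) -Inf)
  upper <- c(16, 1e5, 20, if (dilution_heat) Inf)
  best <- NULL
  for (lka in log10_ka_starts) {
    p0 <- c(lka, if (is.finite(dh0) && dh0 != 0) dh0 else -50, 1,
            if (dilution_heat) 0)
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    chi2 <- sum(res$fvec^2)
    if (is.null(best) || chi2 < best$chi2)
      best <- list(par = res$par, chi2 = chi2, info = res$info)
  }
  if (is.null(best)) stop("ITC fit failed to converge from any start")
  p <- best$par
  jac <- .num_jacobian(resid_fn, p)
  npar <- length(p)
  dof <- length(obs) - npar
  s2 <- if (dof > 0) best$chi2 / dof else 0
  cov <- tryCatch(solve(crossprod(jac)) * s2,
                  error = function(e) matrix(NA_real_, npar, npar))
  se <- sqrt(pmax(diag(cov), 0))
  ka <- 10^p[1]
  ka_se <- ka * log(10) * se[1]  # delta method on log10 K_A
  out <- list(ka = ka, ka_se = ka_se, delta_h = p[2], delta_h_se = se[2],
              n = p[3], n_se = se[3],
              dilution_heat = if (dilution_heat) p[4] else NULL,
              coefficients = c(ka = ka, delta_h = p[2], n = p[3]),
              chi2 = best$chi2 * scale0^2, dof = dof,
              experiment = experiment,
              fitted_heats = one_site_itc_heats(ka, p[2], p[3],
                                                experiment)$heats +
                if (dilution_heat) p[4] else 0,
              call = match.call())
  class(out) <- "itc_fit"
  out
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("One-site ITC fit\n")
  cat(sprintf("  K_A = %.3g +/- %.2g 1/M\n", x$ka, x$ka_se))
  cat(sprintf("  dH  = %.2f +/- %.2g kJ/mol\n", x$delta_h, x$delta_h_se))
  cat(sprintf("  n   = %.3f +/- %.2g\n", x$n, x$n_se))
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  print(object)
  dg <- gibbs_from_ka(object$ka, object$experiment$temperature)
  cat(sprintf("  dG  = %.2f kJ/mol, TdS = %.2f kJ/mol at %.1f K\n",
              dg, entropy_term(object$delta_h, dg),
              object$experiment$temperature))
  invisible(object)
}

#' @export
coef.itc_fit <- function(object, ...) object$coefficients

#' @export
fitted.itc_fit <- function(object, ...) object$fitted_heats

#' @export
residuals.itc_fit <- function(object, ...)
  object$experiment$heats - object$fitted_heats

#' @export
predict.itc_fit <- function(object, experiment = NULL, ...) {
  if (is.null(experiment)) return(object$fitted_heats)
  one_site_itc_heats(object$ka, object$delta_h, object$n, experiment)$heats
}

#' Plot an ITC isotherm and its fit
#'
#' Normalised heat per mole of injectant versus molar ratio, with the fitted
#' curve.
#' @param x An `itc_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.itc_fit <- function(x, ...) {
  ex <- x$experiment
  inj_mol <- ex$syringe_concentration * ex$injection_volumes
  mdl <- one_site_itc_heats(x$ka, x$delta_h, x$n, ex)
  ratio <- mdl$titrant_total / mdl$macromolecule_total
  graphics::plot(ratio, ex$heats / inj_mol / 1000,
                 xlab = "molar ratio (titrant/macromolecule)",
                 ylab = "kJ per mol of injectant", pch = 16, ...)
  graphics::lines(ratio, x$fitted_heats / inj_mol / 1000, col = 2)
  invisible(x)
}

#' Assemble a binding-thermodynamics record
#'
#' Computes `dG` from `K_A` and the entropic term from the identity
#' `dG = dH - T dS`, which therefore holds exactly for every record.
#'
#' @param ka Association constant, 1/M.
#' @param delta_h Binding enthalpy, kJ/mol.
#' @param temperature Temperature, K.
#' @param ka_se,delta_h_se,delta_cp,delta_cp_se Optional errors and
#'   heat-capacity change (kJ/mol/K).
#' @return An object of class `binding_thermodynamics`.
#' @export
binding_thermodynamics <- function(ka, delta_h, temperature, ka_se = NA,
                                   delta_h_se = NA, delta_cp = NA,
                                   delta_cp_se = NA) {
  dg <- gibbs_from_ka(ka, temperature)
  structure(list(temperature = temperature, ka = ka, ka_se = ka_se,
                 delta_g = dg, delta_h = delta_h, delta_h_se = delta_h_se,
                 t_delta_s = entropy_term(delta_h, dg),
                 delta_cp = delta_cp, delta_cp_se = delta_cp_se),
            class = "binding_thermodynamics")
}

#' @export
print.binding_thermodynamics <- function(x, ...) {
  cat(sprintf("Binding thermodynamics at %.1f K\n", x$temperature))
  cat(sprintf("  K_A = %.3g 1/M\n", x$ka))
  cat(sprintf("  dG  = %.2f kJ/mol\n", x$delta_g))
  cat(sprintf("  dH  = %.2f kJ/mol\n", x$delta_h))
  cat(sprintf("  TdS = %.2f kJ/mol\n", x$t_delta_s))
  if (is.finite(x$delta_cp))
    cat(sprintf("  dCp = %.2f kJ/mol/K\n", x$delta_cp))
  invisible(x)
}

#' A DSC heat-capacity trace
#'
#' @param temperatures Strictly increasing temperature grid, K.
#' @param cp Molar heat capacity at each point, kJ/(mol K).
#' @param baseline Optional baseline on the same grid.
#' @return An object of class `dsc_trace`.
#' @export
dsc_trace <- function(temperatures, cp, baseline = NULL) {
  stopifnot(length(temperatures) == length(cp))
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  if (!is.null(baseline)) stopifnot(length(baseline) == length(cp))
  structure(list(temperatures = temperatures, cp = cp, baseline = baseline),
            class = "dsc_trace")
}

#' Calorimetric enthalpy from a DSC trace
#'
#' Trapezoidal integral of the baseline-corrected heat capacity over
#' temperature.  When no baseline is stored, a straight line is fitted to
#' flanking windows (the first and last `window_frac` of the points); a
#' warning is issued if those windows appear to overlap the transition
#' (excess heat capacity in the window above 5% of the peak).
#'
#' @param trace A [dsc_trace()].
#' @param window_frac Fraction of points in each flanking baseline window.
#' @return Calorimetric enthalpy in kJ/mol.
#' @export
dsc_enthalpy <- function(trace, window_frac = 0.1) {
  stopifnot(inherits(trace, "dsc_trace"))
  tt <- trace$temperatures
  cp <- trace$cp
  bl <- trace$baseline
  if (is.null(bl)) {
    n <- length(tt)
    k <- max(2L, round(window_frac * n))
    idx <- c(seq_len(k), seq(n - k + 1L, n))
    fit <- stats::lm(cp[idx] ~ tt[idx])
    bl <- fit$coefficients[1] + fit$coefficients[2] * tt
    excess_w <- cp[idx] - bl[idx]
    if (max(abs(excess_w)) > 0.05 * max(abs(cp - bl)))
      warning("baseline windows appear to overlap the transition")
  }
  ex <- cp - bl
  sum(diff(tt) * (utils::head(ex, -1) + utils::tail(ex, -1)) / 2)
}
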