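# Global (cluster) fitting of CPMG dispersion curves: residues in a cluster
# share one exchange rate; amplitudes are per residue in ppm units so a single
# parameter set predicts both static fields; intrinsic R2_0 is free per
# residue per field and is profiled out analytically during optimisation.

#' Assemble a dispersion data set
#'
#' Validates and normalises a long-format table of dispersion measurements,
#' one row per (residue, field, nu_cpmg) point.
#'
#' @param x A data.frame with columns `chain`, `residue`, `aa`, `field_mhz`,
#'   `nu_cpmg`, `r2eff` and optionally `sigma`.  If `sigma` is absent it is
#'   estimated from duplicated `nu_cpmg` points within each curve, falling
#'   back to `sigma_floor`.
#' @param sigma_floor Fallback measurement error in 1/s used when `sigma` is
#'   absent and cannot be estimated from duplicates.
#' @return A data.frame of class `dispersion_data` with an extra
#'   `residue_id` column (`"H:R71"` style).
#' @export
dispersion_data <- function(x, sigma_floor = 0.2) {
  need <- c("chain", "residue", "aa", "field_mhz", "nu_cpmg", "r2eff")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)
  x$chain <- as.character(x$chain)
  x$aa <- toupper(as.character(x$aa))
  if (!"sigma" %in% names(x) || all(is.na(x$sigma))) {
    x$sigma <- NA_real_
    key <- interaction(x$chain, x$residue, x$field_mhz, drop = TRUE)
    for (k in levels(key)) {
      i <- key == k
      dup <- duplicated(x$nu_cpmg[i]) | duplicated(x$nu_cpmg[i],
                                                   fromLast = TRUE)
      est <- if (any(dup)) {
        # pooled SD over replicate nu_cpmg points
        sp <- tapply(x$r2eff[i][dup], x$nu_cpmg[i][dup], stats::sd)
        sqrt(mean(sp^2, na.rm = TRUE))
      } else NA_real_
      x$sigma[i] <- if (is.finite(est) && est > 0) est else sigma_floor
    }
  }
  if (any(!is.finite(x$sigma) | x$sigma <= 0))
    stop("sigma must be > 0 for every point")
  if (any(x$nu_cpmg <= 0)) stop("nu_cpmg must be > 0")
  x$residue_id <- sprintf("%s:%s%d", x$chain, x$aa, as.integer(x$residue))
  npts <- table(interaction(x$residue_id, x$field_mhz, drop = TRUE))
  if (any(npts < 4))
    stop("every residue/field curve needs >= 4 points")
  class(x) <- c("dispersion_data", "data.frame")
  x
}

#' Read a dispersion table from delimited text
#'
#' Whitespace- or tab-delimited text with a header line naming the columns
#' `chain residue aa field_mhz nu_cpmg r2eff sigma`; lines starting with `#`
#' are comments.
#'
#' @param path File path.
#' @param ... Passed on to [dispersion_data()].
#' @return A `dispersion_data` data.frame.
#' @export
read_dispersion_table <- function(path, ...) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  dispersion_data(df, ...)
}

#' Write a dispersion table to delimited text
#'
#' @param x A `dispersion_data` data.frame (or compatible).
#' @param path Output file path.
#' @export
write_dispersion_table <- function(x, path) {
  cols <- c("chain", "residue", "aa", "field_mhz", "nu_cpmg", "r2eff", "sigma")
  utils::write.table(x[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Exclude flat dispersion curves
#'
#' Implements the standard pre-fit filter: a residue is kept only if its
#' effective R2 changed by at least `min_range` (default 1/s) over the whole
#' CPMG frequency range on at least one static field; residues whose R2
#' changed by less than that on every field are excluded.  The partition is
#' exhaustive and disjoint, idempotent, and independent of row order.
#'
#' @param data A `dispersion_data` data.frame.
#' @param min_range Minimum max-min range of R2eff in 1/s (strict `<`
#'   excludes).
#' @return A list with elements `kept` and `excluded` (both
#'   `dispersion_data`, possibly zero-row) and `summary`, a per-residue
#'   data.frame of the largest per-field range and the decision.
#' @export
exclude_flat_curves <- function(data, min_range = 1.0) {
  stopifnot(nrow(data) > 0)
  ids <- unique(data$residue_id)
  rng <- vapply(ids, function(id) {
    d <- data[data$residue_id == id, ]
    max(tapply(d$r2eff, d$field_mhz, function(v) max(v) - min(v)))
  }, numeric(1))
  keep_id <- ids[rng >= min_range]
  summary <- data.frame(residue_id = ids, max_range = unname(rng),
                        kept = ids %in% keep_id, row.names = NULL)
  list(kept = data[data$residue_id %in% keep_id, , drop = FALSE],
       excluded = data[!data$residue_id %in% keep_id, , drop = FALSE],
       summary = summary)
}

# model curve with r2_0 = 0 for one residue at one field
.disp_curve0 <- function(nu, model, kex, amp, p_minor, field) {
  if (model == "luz_meiboom") {
    luz_meiboom_r2eff(nu, exchange_params(0, kex, phi_ppm2 = amp), field)
  } else {
    carver_richards_r2eff(
      nu, exchange_params(0, kex, p_minor = p_minor, delta_omega_ppm = amp),
      field)
  }
}

# curve index: one row per (residue, field) with point row indices
.curve_index <- function(data) {
  key <- interaction(data$residue_id, data$field_mhz, drop = TRUE)
  idx <- split(seq_len(nrow(data)), key)
  info <- do.call(rbind, lapply(idx, function(i)
    data.frame(residue_id = data$residue_id[i[1]],
               field_mhz = data$field_mhz[i[1]])))
  info$rows <- I(idx)
  rownames(info) <- NULL
  info
}

#' Globally fit dispersion curves of a residue cluster
#'
#' Weighted least-squares fit of a two-state exchange model to all curves in
#' `data`, minimising `sum(((obs - model)/sigma)^2)`.  All residues share a
#' single exchange rate `k_ex` (this is the clustering assumption: neighbouring
#' residues fluctuate together); the amplitude (`phi_ppm2` for the
#' fast-exchange model, `delta_omega_ppm` for Carver-Richards) is per residue
#' and specified in ppm so that one parameter set predicts every field;
#' `r2_0` is free per residue per field.  For Carver-Richards, `p_minor` is
#' shared across the cluster by default and can be released per residue.
#'
#' A multi-start strategy over a log-spaced `k_ex` grid guards against local
#' minima; the best final chi-square is returned.  Parameter errors come from
#' the covariance at the optimum (inverse of J'J of the sigma-scaled
#' residuals).
#'
#' @param data A `dispersion_data` data.frame (or coercible via
#'   [dispersion_data()]).
#' @param model `"luz_meiboom"` (fast exchange) or `"carver_richards"`.
#' @param share_p_minor For Carver-Richards: share `p_minor` across the
#'   cluster (default) or fit one per residue.
#' @param kex_starts Numeric vector of `k_ex` start values in 1/s; default 8
#'   log-spaced values between 50 and 5000.
#' @param kex_bounds Box bounds on `k_ex` during optimisation.
#' @param jackknife If `TRUE`, add leave-one-point-out jackknife errors for
#'   `k_ex` (slow; covariance errors are always reported).
#' @return An object of class `dispersion_fit`; see
#'   [summary.dispersion_fit()], [coef.dispersion_fit()],
#'   [predict.dispersion_fit()], [plot.dispersion_fit()].
#' @examples
#' sim <- gen_dispersion_dataset(dispersion_scenario(
#'   clusters = list(list(k_ex = 840, model = "luz_meiboom", n_residues = 2)),
#'   n_decoys = 0, seed = 1))
#' fit <- fit_dispersion(sim$curves, model = "luz_meiboom")
#' coef(fit)["k_ex"]
#' @export
fit_dispersion <- function(data,
                           model = c("luz_meiboom", "carver_richards"),
                           share_p_minor = TRUE,
                           kex_starts = NULL,
                           kex_bounds = c(10, 5e4),
                           jackknife = FALSE) {
  model <- match.arg(model)
  if (!inherits(data, "dispersion_data")) data <- dispersion_data(data)
  if (is.null(kex_starts))
    kex_starts <- exp(seq(log(50), log(5000), length.out = 8))
  curves <- .curve_index(data)
  residues <- unique(data$residue_id)
  nres <- length(residues)
  fields <- lapply(curves$field_mhz, field_context)
  obs <- data$r2eff
  sig <- data$sigma

  # nonlinear parameter layout:
  #   [1] k_ex; then per-residue amplitude; then p_minor (shared or per res)
  amp_ix <- 1L + seq_len(nres)
  n_nl <- 1L + nres
  pm_ix <- integer(0)
  if (model == "carver_richards") {
    pm_ix <- if (share_p_minor) n_nl + 1L else n_nl + seq_len(nres)
    n_nl <- n_nl + length(pm_ix)
  }

  amp_of <- function(theta, res) theta[amp_ix[match(res, residues)]]
  pm_of <- function(theta, res) {
    if (model != "carver_richards") return(NULL)
    if (share_p_minor) theta[pm_ix] else theta[pm_ix[match(res, residues)]]
  }

  # residuals with r2_0 profiled out per curve (weighted mean of obs - g)
  profiled_resid <- function(theta) {
    r <- numeric(nrow(data))
    for (ci in seq_len(nrow(curves))) {
      rows <- curves$rows[[ci]]
      g <- .disp_curve0(data$nu_cpmg[rows], model, theta[1],
                        amp_of(theta, curves$residue_id[ci]),
                        pm_of(theta, curves$residue_id[ci]), fields[[ci]])
      w <- 1 / sig[rows]^2
      r2_0 <- sum(w * (obs[rows] - g)) / sum(w)
      r[rows] <- (obs[rows] - g - r2_0) / sig[rows]
    }
    r
  }

  # rough amplitude initialisation from the observed dispersion range
  amp_init <- function(kex) {
    vapply(residues, function(id) {
      d <- data[data$residue_id == id, ]
      rex_obs <- max(tapply(d$r2eff, d$field_mhz, function(v) max(v) - min(v)))
      f <- field_context(stats::median(d$field_mhz))
      w1 <- ppm_to_rad(1, f)
      if (model == "luz_meiboom") {
        max(rex_obs * kex / w1^2, 1e-4)
      } else {
        pm0 <- 0.03
        min(max(sqrt(rex_obs * kex / (pm0 * (1 - pm0))) / w1, 0.05), 10)
      }
    }, numeric(1))
  }

  lower <- c(kex_bounds[1], rep(1e-6, nres),
             rep(1e-4, length(pm_ix)))
  upper <- c(kex_bounds[2],
             rep(if (model == "luz_meiboom") 10 else 20, nres),
             rep(0.5, length(pm_ix)))

  best <- NULL
  starts_log <- data.frame(k_ex_start = kex_starts, chi2 = NA_real_,
                           converged = NA)
  for (si in seq_along(kex_starts)) {
    th0 <- c(kex_starts[si], amp_init(kex_starts[si]),
             rep(0.03, length(pm_ix)))
    res <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                         fn = profiled_resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-10, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) next
    chi2 <- sum(res$fvec^2)
    starts_log$chi2[si] <- chi2
    starts_log$converged[si] <- res$info %in% 1:4
    if (is.null(best) || chi2 < best$chi2)
      best <- list(theta = res$par, chi2 = chi2, info = res$info)
  }
  if (is.null(best))
    stop("global dispersion fit failed to converge from any start")

  theta <- best$theta
  # recover profiled r2_0 values
  r2_0_tab <- do.call(rbind, lapply(seq_len(nrow(curves)), function(ci) {
    rows <- curves$rows[[ci]]
    g <- .disp_curve0(data$nu_cpmg[rows], model, theta[1],
                      amp_of(theta, curves$residue_id[ci]),
                      pm_of(theta, curves$residue_id[ci]), fields[[ci]])
    w <- 1 / sig[rows]^2
    data.frame(residue_id = curves$residue_id[ci],
               field_mhz = curves$field_mhz[ci],
               r2_0 = sum(w * (obs[rows] - g)) / sum(w))
  }))

  # full (unprofiled) parameter vector for the covariance
  full <- c(theta, r2_0_tab$r2_0)
  full_resid <- function(p) {
    th <- p[seq_len(n_nl)]
    r20 <- p[n_nl + seq_len(nrow(curves))]
    r <- numeric(nrow(data))
    for (ci in seq_len(nrow(curves))) {
      rows <- curves$rows[[ci]]
      g <- .disp_curve0(data$nu_cpmg[rows], model, th[1],
                        amp_of(th, curves$residue_id[ci]),
                        pm_of(th, curves$residue_id[ci]), fields[[ci]])
      r[rows] <- (obs[rows] - g - r20[ci]) / sig[rows]
    }
    r
  }
  jac <- .num_jacobian(full_resid, full,
                       lower = c(lower, rep(-Inf, nrow(curves))),
                       upper = c(upper, rep(Inf, nrow(curves))))
  cov <- tryCatch(solve(crossprod(jac)), error = function(e) {
    warning("singular information matrix; parameter errors unavailable")
    matrix(NA_real_, length(full), length(full))
  })
  se <- sqrt(pmax(diag(cov), 0))

  nm <- c("k_ex",
          paste0(if (model == "luz_meiboom") "phi_ppm2." else "dw_ppm.",
                 residues),
          if (model == "carver_richards") {
            if (share_p_minor) "p_minor" else paste0("p_minor.", residues)
          },
          paste0("r2_0.", r2_0_tab$residue_id, ".", r2_0_tab$field_mhz))
  names(full) <- names(se) <- nm

  n_free <- length(full)
  dof <- nrow(data) - n_free
  if (dof <= 0) stop("invalid design: dof <= 0 (", nrow(data), " points, ",
                     n_free, " parameters)")

  jk <- NULL
  if (jackknife) {
    kx <- vapply(seq_len(nrow(data)), function(drop_i) {
      d2 <- data[-drop_i, , drop = FALSE]
      f2 <- tryCatch(fit_dispersion(d2, model = model,
                                    share_p_minor = share_p_minor,
                                    kex_starts = theta[1],
                                    kex_bounds = kex_bounds),
                     error = function(e) NULL)
      if (is.null(f2)) NA_real_ else f2$k_ex
    }, numeric(1))
    kx <- kx[is.finite(kx)]
    n <- length(kx)
    jk <- sqrt((n - 1) / n * sum((kx - mean(kx))^2))
  }

  per_res <- data.frame(residue_id = residues,
                        amplitude = theta[amp_ix],
                        amplitude_se = se[amp_ix],
                        row.names = NULL)
  names(per_res)[2:3] <- if (model == "luz_meiboom")
    c("phi_ppm2", "phi_ppm2_se") else c("dw_ppm", "dw_ppm_se")

  structure(list(
    model = model, share_p_minor = share_p_minor,
    residues = residues, data = data,
    k_ex = unname(theta[1]), k_ex_se = unname(se[1]),
    p_minor = if (length(pm_ix)) unname(theta[pm_ix]) else NULL,
    p_minor_se = if (length(pm_ix)) unname(se[pm_ix]) else NULL,
    per_residue = per_res, r2_0 = r2_0_tab,
    coefficients = full, parameter_errors = se, cov = cov,
    chi2 = best$chi2, dof = dof, reduced_chi2 = best$chi2 / dof,
    n_points = nrow(data), n_free = n_free,
    starts = starts_log, k_ex_se_jackknife = jk,
    call = match.call()),
    class = "dispersion_fit")
}

# forward-difference jacobian of a vector-valued function; steps backward
# when a forward step would leave the feasible box
.num_jacobian <- function(fn, x, eps = 1e-6, lower = NULL, upper = NULL) {
  f0 <- fn(x)
  jac <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1e-3)
    if (!is.null(upper) && x[j] + h > upper[j]) h <- -h
    if (!is.null(lower) && x[j] + h < lower[j]) h <- abs(h)
    xp <- x; xp[j] <- xp[j] + h
    jac[, j] <- (fn(xp) - f0) / h
  }
  jac
}

#' Reduced chi-square of a fit
#'
#' @param fit A `dispersion_fit`, `itc_fit`, or any list with numeric
#'   elements `chi2` and `dof`.
#' @return `chi2 / dof`.
#' @export
reduced_chi2 <- function(fit) {
  if (is.null(fit$chi2) || is.null(fit$dof))
    stop("fit must carry chi2 and dof")
  if (fit$dof <= 0) stop("dof must be > 0")
  fit$chi2 / fit$dof
}

#' F-test between nested dispersion fits
#'
#' Compares a simpler and a more complex fit of the same data:
#' `F = ((chi2_s - chi2_c)/(dof_s - dof_c)) / (chi2_c/dof_c)`, with the
#' complex model selected iff `p < alpha`.  Ties or a negative numerator
#' select the simple model.
#'
#' @param fit_simple,fit_complex Two fits of identical data;
#'   `fit_complex` must have more free parameters.
#' @param alpha Significance level (default 0.05).
#' @return A list of class `f_test` with `selected` (`"simple"` or
#'   `"complex"`), `f`, `p_value`, and the degrees of freedom.
#' @export
f_test_select <- function(fit_simple, fit_complex, alpha = 0.05) {
  if (fit_simple$n_points != fit_complex$n_points)
    stop("fits are not comparisons of identical data")
  ds <- function(f) {
    d <- f$data
    d <- d[order(d$residue_id, d$field_mhz, d$nu_cpmg), ]
    d[, c("residue_id", "field_mhz", "nu_cpmg", "r2eff", "sigma")]
  }
  a <- ds(fit_simple); b <- ds(fit_complex)
  rownames(a) <- rownames(b) <- NULL
  if (!isTRUE(all.equal(a, b, tolerance = 1e-12)))
    stop("fits are not comparisons of identical data")
  if (fit_complex$dof >= fit_simple$dof)
    stop("fit_complex must have more free parameters than fit_simple")
  dnum <- fit_simple$dof - fit_complex$dof
  num <- (fit_simple$chi2 - fit_complex$chi2) / dnum
  den <- fit_complex$chi2 / fit_complex$dof
  f <- num / den
  if (!is.finite(f) || f <= 0) {
    out <- list(selected = "simple", f = max(f, 0), p_value = 1,
                df1 = dnum, df2 = fit_complex$dof, alpha = alpha)
  } else {
    p <- stats::pf(f, dnum, fit_complex$dof, lower.tail = FALSE)
    out <- list(selected = if (p < alpha) "complex" else "simple",
                f = f, p_value = p, df1 = dnum, df2 = fit_complex$dof,
                alpha = alpha)
  }
  class(out) <- "f_test"
  out
}

#' @export
print.f_test <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.4g, p = %.4g -> %s model\n",
              x$df1, x$df2, x$f, x$p_value, x$selected))
  invisible(x)
}

#' Search over candidate residue clusterings
#'
#' Fits every candidate partition (each group fitted globally with its own
#' shared exchange rate), ranks partitions by total reduced chi-square, and
#' reports F tests between nested alternatives (a partition refines another
#' when each of its groups is contained in one group of the other).
#'
#' @param data A `dispersion_data` data.frame.
#' @param partitions A list of partitions; each partition is a list of
#'   character vectors of residue ids that together cover the same residue
#'   set.
#' @param model,share_p_minor,kex_starts Passed to [fit_dispersion()].
#' @return A list of class `cluster_search` with the ranked `table`, the
#'   per-partition `fits`, `best` (index of the winning partition) and
#'   `f_tests`.
#' @export
cluster_search <- function(data, partitions,
                           model = c("luz_meiboom", "carver_richards"),
                           share_p_minor = TRUE, kex_starts = NULL) {
  model <- match.arg(model)
  if (!length(partitions)) stop("partitions must be non-empty")
  if (!inherits(data, "dispersion_data")) data <- dispersion_data(data)
  all_ids <- sort(unique(data$residue_id))
  for (p in partitions) {
    got <- sort(unique(unlist(p)))
    if (!identical(got, all_ids))
      stop("every partition must cover the same residue set")
  }
  fits <- lapply(partitions, function(p) {
    lapply(p, function(grp)
      fit_dispersion(data[data$residue_id %in% grp, , drop = FALSE],
                     model = model, share_p_minor = share_p_minor,
                     kex_starts = kex_starts))
  })
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    chi2 <- sum(vapply(fits[[i]], `[[`, numeric(1), "chi2"))
    dof <- sum(vapply(fits[[i]], `[[`, numeric(1), "dof"))
    data.frame(partition = i, n_groups = length(fits[[i]]),
               chi2 = chi2, dof = dof, reduced_chi2 = chi2 / dof)
  }))
  refines <- function(fine, coarse) {
    all(vapply(fine, function(g)
      any(vapply(coarse, function(G) all(g %in% G), logical(1))),
      logical(1)))
  }
  ft <- list()
  for (i in seq_along(partitions)) for (j in seq_along(partitions)) {
    if (i == j) next
    if (length(partitions[[j]]) > length(partitions[[i]]) &&
        refines(partitions[[j]], partitions[[i]])) {
      fs <- list(chi2 = tab$chi2[i], dof = tab$dof[i],
                 n_points = nrow(data), data = data)
      fc <- list(chi2 = tab$chi2[j], dof = tab$dof[j],
                 n_points = nrow(data), data = data)
      ft[[length(ft) + 1L]] <- c(simple = i, complex = j,
                                 f_test_select(fs, fc))
    }
  }
  structure(list(table = tab[order(tab$reduced_chi2), ],
                 fits = fits, best = tab$partition[which.min(tab$reduced_chi2)],
                 f_tests = ft, partitions = partitions),
            class = "cluster_search")
}

#' @export
print.cluster_search <- function(x, ...) {
  cat("Cluster search over", length(x$partitions), "partitions\n")
  print(x$table, row.names = FALSE)
  cat("best partition:", x$best, "\n")
  invisible(x)
}

# ---- dispersion_fit S3 methods ---------------------------------------------

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("Global two-state dispersion fit (%s)\n", x$model))
  cat(sprintf("  %d residues, %d points, chi2 = %.4g, red. chi2 = %.3f\n",
              length(x$residues), x$n_points, x$chi2, x$reduced_chi2))
  cat(sprintf("  shared k_ex = %.1f +/- %.1f 1/s\n", x$k_ex, x$k_ex_se))
  if (!is.null(x$p_minor) && x$share_p_minor)
    cat(sprintf("  shared p_minor = %.4f +/- %.4f\n",
                x$p_minor, x$p_minor_se))
  invisible(x)
}

#' Summary of a global dispersion fit
#'
#' @param object A `dispersion_fit`.
#' @param ... Unused.
#' @export
summary.dispersion_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.dispersion_fit")
}

#' @export
print.summary.dispersion_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-residue parameters:\n")
  print(f$per_residue, row.names = FALSE, digits = 4)
  cat("\nIntrinsic rates (r2_0, 1/s):\n")
  print(f$r2_0, row.names = FALSE, digits = 4)
  cat("\nMulti-start log:\n")
  print(f$starts, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
coef.dispersion_fit <- function(object, ...) object$coefficients

#' Predicted dispersion curves from a fitted cluster model
#'
#' @param object A `dispersion_fit`.
#' @param newdata Data frame with columns `residue_id`, `field_mhz`,
#'   `nu_cpmg`; defaults to the fitted data.
#' @param ... Unused.
#' @return Numeric vector of predicted effective R2 values.
#' @export
predict.dispersion_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  vapply(seq_len(nrow(newdata)), function(i) {
    id <- newdata$residue_id[i]
    fm <- newdata$field_mhz[i]
    k <- match(id, object$residues)
    if (is.na(k)) stop("unknown residue_id: ", id)
    ri <- which(object$r2_0$residue_id == id & object$r2_0$field_mhz == fm)
    if (!length(ri)) stop("no fitted r2_0 for ", id, " at ", fm, " MHz")
    pm <- if (is.null(object$p_minor)) NULL else
      if (object$share_p_minor) object$p_minor else object$p_minor[k]
    object$r2_0$r2_0[ri] +
      .disp_curve0(newdata$nu_cpmg[i], object$model, object$k_ex,
                   object$per_residue[[2]][k], pm, field_context(fm))
  }, numeric(1))
}

#' @export
fitted.dispersion_fit <- function(object, ...) predict(object)

#' Residuals of a dispersion fit
#'
#' @param object A `dispersion_fit`.
#' @param type `"pearson"` (sigma-scaled, default) or `"response"`.
#' @param ... Unused.
#' @export
residuals.dispersion_fit <- function(object,
                                     type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$data$r2eff - fitted(object)
  if (type == "pearson") r / object$data$sigma else r
}

#' Plot fitted dispersion curves
#'
#' One panel per residue; points with error bars, fitted model curves as
#' lines, one colour per static field.
#'
#' @param x A `dispersion_fit`.
#' @param residues Residue ids to plot (default: all, up to 12).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dispersion_fit <- function(x, residues = NULL, ...) {
  if (is.null(residues)) residues <- utils::head(x$residues, 12)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(residues)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (id in residues) {
    d <- x$data[x$data$residue_id == id, ]
    flds <- sort(unique(d$field_mhz))
    cols <- stats::setNames(seq_along(flds) + 1, flds)
    graphics::plot(d$nu_cpmg, d$r2eff,
                   col = cols[as.character(d$field_mhz)], pch = 16,
                   xlab = expression(nu[CPMG] ~ "(Hz)"),
                   ylab = expression(R[2 * ",eff"] ~ (s^-1)),
                   main = id, ...)
    graphics::arrows(d$nu_cpmg, d$r2eff - d$sigma, d$nu_cpmg,
                     d$r2eff + d$sigma, angle = 90, code = 3, length = 0.02,
                     col = cols[as.character(d$field_mhz)])
    for (fm in flds) {
      nu <- seq(min(d$nu_cpmg), max(d$nu_cpmg), length.out = 100)
      pr <- predict(x, data.frame(residue_id = id, field_mhz = fm,
                                  nu_cpmg = nu))
      graphics::lines(nu, pr, col = cols[as.character(fm)])
    }
  }
  invisible(x)
}

#' Simulate replicate data sets from a fitted dispersion model
#'
#' Draws Gaussian noise with the per-point `sigma` around the fitted curves.
#'
#' @param object A `dispersion_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `dispersion_data` data.frames.
#' @export
simulate.dispersion_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  lapply(seq_len(nsim), function(i) {
    d <- object$data
    d$r2eff <- mu + stats::rnorm(length(mu), 0, d$sigma)
    d
  })
}

#' Write a fit report as delimited text
#'
#' One row per free parameter with its estimate and standard error, plus
#' chi-square diagnostics as comment lines.
#'
#' @param fit A `dispersion_fit`.
#' @param path Output path.
#' @export
write_fit_report <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# model: %s", fit$model), con)
  writeLines(sprintf("# chi2: %.10g  dof: %d  reduced_chi2: %.10g",
                     fit$chi2, fit$dof, fit$reduced_chi2), con)
  df <- data.frame(parameter = names(fit$coefficients),
                   estimate = unname(fit$coefficients),
                   se = unname(fit$parameter_errors))
  utils::write.table(format(df, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
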