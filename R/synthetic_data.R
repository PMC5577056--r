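# Seeded generators for every input the pipeline consumes, each emitting its
# ground truth alongside the data.  All randomness flows through a single
# integer seed; each generator draws from its own deterministic substream
# (seed + a per-kind offset) of R's Mersenne-Twister, so the different data
# kinds are independent and bit-reproducible.  The caller's RNG state is
# saved and restored.

.SUBSTREAM <- c(dispersion = 101L, itc = 211L, annotation = 307L,
                ensemble = 401L)

with_substream <- function(seed, kind, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) + .SUBSTREAM[[kind]], kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  force(expr)
}

LARGE_AA <- setdiff(AA1, SMALL_RESIDUES)

#' Scenario for the dispersion-data generator
#'
#' Default scenario: two residue clusters fluctuating at the two wild-type
#' exchange rates (840 and 2033 1/s), measured at 600.13 and 750.13 MHz on a
#' 12-point CPMG grid (25-1000 Hz, 40 ms constant-time period) with Gaussian
#' noise of 0.3 1/s, plus four flat decoy residues.
#'
#' @param clusters List of cluster definitions; each is a list with `k_ex`
#'   (1/s), `model` (`"carver_richards"` or `"luz_meiboom"`), `n_residues`,
#'   and optionally `chain`, `p_minor` (CR), `dw_ppm_range` (CR) or
#'   `phi_ppm2_range` (LM).
#' @param fields Proton frequencies in MHz.
#' @param nu_cpmg CPMG frequency grid in Hz.
#' @param relaxation_period Constant-time period in s.
#' @param sigma Gaussian noise SD on R2eff, 1/s.
#' @param r2_0_range Range from which per-curve intrinsic rates are drawn.
#' @param n_decoys Number of flat (non-dispersive) decoy residues.
#' @param decoy_rex Upper bound on decoy dispersion amplitude, 1/s.
#' @param seed Integer seed.
#' @return A scenario list for [gen_dispersion_dataset()].
#' @export
dispersion_scenario <- function(
    clusters = list(
      list(k_ex = 840, model = "carver_richards", n_residues = 10,
           chain = "H", p_minor = 0.03, dw_ppm_range = c(0.5, 2)),
      list(k_ex = 2033, model = "carver_richards", n_residues = 10,
           chain = "L", p_minor = 0.03, dw_ppm_range = c(0.5, 2))),
    fields = c(600.13, 750.13),
    nu_cpmg = c(25, 50, 75, 100, 150, 200, 300, 400, 500, 650, 800, 1000),
    relaxation_period = 0.04,
    sigma = 0.3,
    r2_0_range = c(12, 18),
    n_decoys = 4,
    decoy_rex = 0.4,
    seed = 1) {
  list(clusters = clusters, fields = fields, nu_cpmg = nu_cpmg,
       relaxation_period = relaxation_period, sigma = sigma,
       r2_0_range = r2_0_range, n_decoys = n_decoys, decoy_rex = decoy_rex,
       seed = seed)
}

#' Generate a synthetic clustered dispersion data set
#'
#' Curves are generated from the closed-form two-state models (one shared
#' exchange rate per cluster, per-residue amplitudes in ppm so both fields
#' derive from one parameter set) plus Gaussian noise.  Decoy residues are
#' non-dispersive (amplitude below `decoy_rex`); their noise is redrawn until
#' the realised curve range stays below 1 1/s on every field, so they are
#' removed by [exclude_flat_curves()] by construction.
#'
#' @param config A [dispersion_scenario()].
#' @return List with `curves` (a [dispersion_data()] frame) and `truth`
#'   (generating parameters: per-cluster `k_ex` and membership, per-residue
#'   amplitudes and intrinsic rates).
#' @export
gen_dispersion_dataset <- function(config = dispersion_scenario()) {
  # recorded measurement error stays positive even for noiseless scenarios
  # (weights would otherwise be degenerate); noise itself uses config$sigma
  sigma_rec <- if (config$sigma > 0) config$sigma else 0.2
  with_substream(config$seed, "dispersion", {
    rows <- list()
    truth_res <- list()
    res_counter <- 0L
    for (ci in seq_along(config$clusters)) {
      cl <- config$clusters[[ci]]
      model <- match.arg(cl$model, c("carver_richards", "luz_meiboom"))
      chain <- if (is.null(cl$chain)) c("H", "L")[1 + (ci - 1) %% 2] else
        cl$chain
      for (ri in seq_len(cl$n_residues)) {
        res_counter <- res_counter + 1L
        resno <- 100L * ci + ri
        aa <- sample(LARGE_AA, 1)
        if (model == "carver_richards") {
          dw <- stats::runif(1, cl$dw_ppm_range[1], cl$dw_ppm_range[2])
          pm <- if (is.null(cl$p_minor)) 0.03 else cl$p_minor
          pars <- function(r2_0) exchange_params(
            r2_0, cl$k_ex, p_minor = pm, delta_omega_ppm = dw)
          amp <- c(dw_ppm = dw, p_minor = pm)
        } else {
          rng <- if (is.null(cl$phi_ppm2_range)) c(0.01, 0.1) else
            cl$phi_ppm2_range
          phi <- stats::runif(1, rng[1], rng[2])
          pars <- function(r2_0) exchange_params(r2_0, cl$k_ex,
                                                 phi_ppm2 = phi)
          amp <- c(phi_ppm2 = phi)
        }
        for (fm in config$fields) {
          r2_0 <- stats::runif(1, config$r2_0_range[1], config$r2_0_range[2])
          f <- field_context(fm)
          mu <- if (model == "carver_richards") {
            carver_richards_r2eff(config$nu_cpmg, pars(r2_0), f)
          } else {
            luz_meiboom_r2eff(config$nu_cpmg, pars(r2_0), f)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            chain = chain, residue = resno, aa = aa, field_mhz = fm,
            nu_cpmg = config$nu_cpmg,
            r2eff = mu + stats::rnorm(length(mu), 0, config$sigma),
            sigma = sigma_rec)
          truth_res[[length(truth_res) + 1L]] <- data.frame(
            residue_id = sprintf("%s:%s%d", chain, aa, resno),
            cluster = ci, model = model, k_ex = cl$k_ex, field_mhz = fm,
            r2_0 = r2_0, t(amp))
        }
      }
    }
    # flat decoys: tiny amplitude, noise constrained below the exclusion rule
    for (di in seq_len(config$n_decoys)) {
      chain <- c("H", "L")[1 + di %% 2]
      resno <- 900L + di
      aa <- sample(AA1, 1)
      phi_decoy <- stats::runif(1, 0, config$decoy_rex) * 840 /
        ppm_to_rad(1, field_context(max(config$fields)))^2
      for (fm in config$fields) {
        r2_0 <- stats::runif(1, config$r2_0_range[1], config$r2_0_range[2])
        f <- field_context(fm)
        mu <- luz_meiboom_r2eff(
          config$nu_cpmg, exchange_params(r2_0, 840, phi_ppm2 = phi_decoy), f)
        for (try in 1:1000) {
          y <- mu + stats::rnorm(length(mu), 0, config$sigma)
          if (max(y) - min(y) < 1.0) break
        }
        if (max(y) - min(y) >= 1.0)
          warning("decoy curve could not be constrained below the exclusion rule")
        rows[[length(rows) + 1L]] <- data.frame(
          chain = chain, residue = resno, aa = aa, field_mhz = fm,
          nu_cpmg = config$nu_cpmg, r2eff = y, sigma = sigma_rec)
        truth_res[[length(truth_res) + 1L]] <- data.frame(
          residue_id = sprintf("%s:%s%d", chain, aa, resno),
          cluster = NA_integer_, model = "decoy", k_ex = NA_real_,
          field_mhz = fm, r2_0 = r2_0, phi_ppm2 = phi_decoy)
      }
    }
    curves <- dispersion_data(do.call(rbind, rows))
    per_res <- do.call(function(...) rbind(...,
                                           make.row.names = FALSE),
                       lapply(truth_res, function(d) {
                         for (cc in c("dw_ppm", "p_minor", "phi_ppm2"))
                           if (!cc %in% names(d)) d[[cc]] <- NA_real_
                         d[, c("residue_id", "cluster", "model", "k_ex",
                               "field_mhz", "r2_0", "dw_ppm", "p_minor",
                               "phi_ppm2")]
                       }))
    clusters_truth <- data.frame(
      cluster = seq_along(config$clusters),
      k_ex = vapply(config$clusters, `[[`, numeric(1), "k_ex"),
      model = vapply(config$clusters, `[[`, character(1), "model"))
    ur <- unique(per_res[!is.na(per_res$cluster),
                         c("residue_id", "cluster")])
    list(curves = curves,
         truth = list(clusters = clusters_truth, per_residue = per_res,
                      members = split(ur$residue_id, ur$cluster),
                      config = config))
  })
}

#' Scenario for the ITC generator
#'
#' Defaults mirror the reference titration: 25 injections of 10 ul of 30 uM
#' titrant into 2 uM macromolecule (1.4 ml cell) at 293.15 K, generated with
#' K_A = 2.0e9 1/M, dH = -99.50 kJ/mol, n = 1.
#'
#' @param ka,delta_h,n Generating thermodynamics.
#' @param cell_concentration,syringe_concentration M.
#' @param cell_volume,injection_volume L.
#' @param n_injections Number of injections.
#' @param temperature K.
#' @param noise_sd Gaussian noise SD on each heat, J (default 0.1 ucal).
#' @param seed Integer seed.
#' @export
itc_scenario <- function(ka = 2.0e9, delta_h = -99.50, n = 1,
                         cell_concentration = 2e-6,
                         syringe_concentration = 30e-6,
                         cell_volume = 1.4e-3, injection_volume = 10e-6,
                         n_injections = 25, temperature = 293.15,
                         noise_sd = 0.1 * 4.184e-6, seed = 1) {
  as.list(environment())
}

#' Generate a synthetic one-site ITC isotherm
#'
#' @param config An [itc_scenario()].
#' @return List with `experiment` (an [itc_experiment()] carrying noisy
#'   heats) and `truth` (the generating `ka`, `delta_h`, `n`).
#' @export
gen_itc_experiment <- function(config = itc_scenario()) {
  with_substream(config$seed, "itc", {
    ex <- itc_experiment(config$cell_concentration,
                         config$syringe_concentration,
                         config$cell_volume,
                         rep(config$injection_volume, config$n_injections),
                         config$temperature)
    mu <- one_site_itc_heats(config$ka, config$delta_h, config$n, ex)$heats
    ex$heats <- mu + stats::rnorm(length(mu), 0, config$noise_sd)
    list(experiment = ex,
         truth = list(ka = config$ka, delta_h = config$delta_h,
                      n = config$n, config = config))
  })
}

#' Scenario for the annotation-fixture generator
#'
#' The default composition mirrors the reference study's bookkeeping: 32
#' fluctuating (dispersive) residues of which exactly 8 satisfy all four
#' selection criteria; the rest fail by CDR location (including a His at
#' L:34, inside CDR-L1), small size, or low accessibility.  The fixture is
#' constructed to match the counts, not the real residue identities.
#'
#' @param n_dispersive Number of dispersive residues.
#' @param n_pass Number designed to pass all criteria.
#' @param n_cdr,n_small Number failing by CDR location / small size (the
#'   remainder fails by low ASA).
#' @param seed Integer seed.
#' @export
annotation_scenario <- function(n_dispersive = 32, n_pass = 8, n_cdr = 10,
                                n_small = 8, seed = 1) {
  as.list(environment())
}

#' Generate a residue-annotation fixture with known selection outcome
#'
#' @param config An [annotation_scenario()].
#' @return List with `annotations` (a [residue_annotation()] frame, rows in
#'   seeded random order) and `expected` (residue ids designed to pass,
#'   re-checked against the selection predicate at generation time).
#' @export
gen_annotation_fixture <- function(config = annotation_scenario()) {
  n_low_asa <- config$n_dispersive - config$n_pass - config$n_cdr -
    config$n_small
  if (config$n_pass < 0 || n_low_asa < 0)
    stop("impossible fixture composition: counts exceed n_dispersive")
  cdr <- kabat_cdr()
  with_substream(config$seed, "annotation", {
    non_cdr_numbers <- function(chain, n) {
      pool <- setdiff(1:110, unlist(mapply(
        seq, cdr$ranges[[chain]]$start, cdr$ranges[[chain]]$end,
        SIMPLIFY = FALSE)))
      sample(pool, n)
    }
    recs <- list()
    add <- function(chain, residue, aa, asa, designed) {
      recs[[length(recs) + 1L]] <<- data.frame(
        chain = chain, residue = residue, aa = aa, asa = asa,
        designed_pass = designed)
    }
    # passing: large, non-CDR, exposed
    ch <- sample(c("H", "L"), config$n_pass, replace = TRUE)
    for (i in seq_len(config$n_pass))
      add(ch[i], non_cdr_numbers(ch[i], 1), sample(LARGE_AA, 1),
          stats::runif(1, 25, 90), TRUE)
    # CDR-located (one is the classic excluded His inside CDR-L1 at L:34)
    if (config$n_cdr > 0) {
      add("L", 34L, "H", stats::runif(1, 25, 90), FALSE)
      for (i in seq_len(config$n_cdr - 1L)) {
        chain <- sample(c("H", "L"), 1)
        r <- cdr$ranges[[chain]]
        k <- sample(nrow(r), 1)
        add(chain, sample(seq(r$start[k], r$end[k]), 1),
            sample(LARGE_AA, 1), stats::runif(1, 25, 90), FALSE)
      }
    }
    # small residues (non-CDR, exposed)
    ch <- sample(c("H", "L"), config$n_small, replace = TRUE)
    for (i in seq_len(config$n_small))
      add(ch[i], non_cdr_numbers(ch[i], 1), sample(SMALL_RESIDUES, 1),
          stats::runif(1, 25, 90), FALSE)
    # buried residues (non-CDR, large, ASA <= 20)
    ch <- sample(c("H", "L"), n_low_asa, replace = TRUE)
    for (i in seq_len(n_low_asa))
      add(ch[i], non_cdr_numbers(ch[i], 1), sample(LARGE_AA, 1),
          stats::runif(1, 2, 18), FALSE)
    df <- do.call(rbind, recs)
    # unique residue numbers within a chain (regenerate clashes)
    for (chain in c("H", "L")) {
      i <- which(df$chain == chain)
      while (any(dup <- duplicated(df$residue[i]))) {
        j <- i[dup]
        in_cdr_row <- in_cdr(df$chain[j], df$residue[j], cdr)
        df$residue[j][!in_cdr_row] <-
          non_cdr_numbers(chain, sum(!in_cdr_row))
        if (any(in_cdr_row)) {
          r <- cdr$ranges[[chain]]
          df$residue[j][in_cdr_row] <- vapply(seq_len(sum(in_cdr_row)),
            function(z) {
              k <- sample(nrow(r), 1)
              sample(seq(r$start[k], r$end[k]), 1)
            }, numeric(1))
        }
        i <- which(df$chain == chain)
      }
    }
    ann <- residue_annotation(
      chain = df$chain, residue = df$residue, aa = df$aa,
      has_dispersion = TRUE, rex = stats::runif(nrow(df), 1, 8),
      in_cdr = in_cdr(df$chain, df$residue, cdr),
      relative_asa = df$asa)
    # independent re-check of the design at generation time
    pass <- ann$has_dispersion & !ann$in_cdr & is_large_residue(ann$aa) &
      ann$relative_asa > 20
    if (!identical(sum(pass), as.integer(config$n_pass)) ||
        !identical(pass, df$designed_pass))
      stop("fixture construction failed its own predicate check")
    ord <- sample(nrow(ann))
    list(annotations = ann[ord, ], expected = sort(ann$residue_id[pass]))
  })
}

#' A small synthetic two-chain backbone
#'
#' Idealised helical Calpha traces with N/C/O/CB atoms for two chains (H and
#' L), used as the default base structure for snapshot ensembles.  Purely
#' geometric and clearly synthetic - not a real protein fold.
#'
#' @param n_res_h,n_res_l Residues per chain.
#' @param offset Inter-chain x-offset in Angstrom.
#' @return List with `atoms` (data.frame: chain, residue, atom, aa) and
#'   `xyz` (matrix of coordinates).
#' @export
synthetic_minifold <- function(n_res_h = 20, n_res_l = 20, offset = 10) {
  build_chain <- function(chain, n, origin) {
    aa_pool <- c("ALA", "LEU", "SER", "ARG", "GLY", "PHE", "GLU", "LYS")
    atoms <- list(); xyz <- list()
    for (i in seq_len(n)) {
      # idealised alpha-helix CA trace: radius 2.3 A, 100 deg/res, 1.5 A rise
      th <- (i - 1) * 100 * pi / 180
      ca <- origin + c(2.3 * cos(th), 2.3 * sin(th), 1.5 * (i - 1))
      aa <- aa_pool[1 + (i - 1) %% length(aa_pool)]
      local_atoms <- rbind(
        N  = ca + c(-0.5, 1.2, -0.9),
        CA = ca,
        C  = ca + c(1.2, 0.3, 0.8),
        O  = ca + c(1.4, 1.3, 1.5),
        CB = ca + c(-1.0, -1.0, 0.5))
      if (aa == "GLY") local_atoms <- local_atoms[1:4, , drop = FALSE]
      for (an in rownames(local_atoms)) {
        atoms[[length(atoms) + 1L]] <- data.frame(
          chain = chain, residue = i, atom = an, aa = aa)
        xyz[[length(xyz) + 1L]] <- local_atoms[an, ]
      }
    }
    list(atoms = do.call(rbind, atoms), xyz = do.call(rbind, xyz))
  }
  h <- build_chain("H", n_res_h, c(0, 0, 0))
  l <- build_chain("L", n_res_l, c(offset, 0, 0))
  list(atoms = rbind(h$atoms, l$atoms), xyz = rbind(h$xyz, l$xyz))
}

#' Scenario for the snapshot-ensemble generator
#'
#' @param base List with `atoms` (data.frame) and `xyz` (matrix) giving the
#'   base coordinates; default a synthetic two-chain helical minifold.
#' @param n_frames Number of snapshot frames (default 130, one per ns of a
#'   130 ns trajectory).
#' @param amplitude Isotropic per-atom Gaussian fluctuation SD, Angstrom.
#' @param seed Integer seed.
#' @export
ensemble_scenario <- function(base = synthetic_minifold(), n_frames = 130,
                              amplitude = 0.5, seed = 1) {
  as.list(environment())
}

#' Generate a Gaussian-perturbed snapshot ensemble
#'
#' Each frame is the base structure with independent isotropic Gaussian
#' displacements of SD `amplitude` on every atom, emulating snapshots
#' extracted from a trajectory.
#'
#' @param config An [ensemble_scenario()].
#' @return List with `ensemble` (a [snapshot_ensemble()]) and `truth`
#'   (the base Calpha-Calpha distance matrix index and per-atom amplitude).
#' @export
gen_snapshot_ensemble <- function(config = ensemble_scenario()) {
  with_substream(config$seed, "ensemble", {
    base <- config$base
    n_atoms <- nrow(base$atoms)
    coords <- array(NA_real_, c(n_atoms, 3, config$n_frames))
    for (f in seq_len(config$n_frames))
      coords[, , f] <- base$xyz +
        matrix(stats::rnorm(3 * n_atoms, 0, config$amplitude), n_atoms, 3)
    ens <- snapshot_ensemble(base$atoms, coords)
    ca <- base$atoms$atom == "CA"
    list(ensemble = ens,
         truth = list(base_xyz = base$xyz, amplitude = config$amplitude,
                      ca_atoms = base$atoms[ca, c("chain", "residue")],
                      config = config))
  })
}
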