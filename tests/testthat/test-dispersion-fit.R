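test_that("flat-curve exclusion applies the 1 1/s rule strictly and cleanly", {
  mk <- function(resno, vals) data.frame(
    chain = "H", residue = resno, aa = "R", field_mhz = 600.13,
    nu_cpmg = seq(25, by = 25, length.out = length(vals)), r2eff = vals,
    sigma = 0.3)
  d <- dispersion_data(rbind(
    mk(1, c(15.8, 15.6, 15.3, 15.0)),      # range 0.8 -> excluded
    mk(2, c(16.0, 15.7, 15.3, 15.0)),      # range exactly 1.0 -> kept
    mk(3, c(15, 15, 15, 15)),              # flat -> excluded
    mk(4, c(19, 17, 16, 15.2))))           # clearly dispersive -> kept
  ex <- exclude_flat_curves(d)
  expect_setequal(unique(ex$kept$residue_id), c("H:R2", "H:R4"))
  expect_setequal(unique(ex$excluded$residue_id), c("H:R1", "H:R3"))
  # exhaustive + disjoint partition
  expect_equal(nrow(ex$kept) + nrow(ex$excluded), nrow(d))
  expect_length(intersect(unique(ex$kept$residue_id),
                          unique(ex$excluded$residue_id)), 0)
  # idempotent
  ex2 <- exclude_flat_curves(ex$kept)
  expect_equal(sort(unique(ex2$kept$residue_id)),
               sort(unique(ex$kept$residue_id)))
  expect_equal(nrow(ex2$excluded), 0)
  # order-independent
  perm <- d[sample(nrow(d)), ]
  ex3 <- exclude_flat_curves(perm)
  expect_setequal(unique(ex3$kept$residue_id), unique(ex$kept$residue_id))
})

test_that("a noiseless fast-exchange curve is recovered exactly", {
  d <- noiseless_lm_curves(k_ex = 1500, phi_ppm2 = 0.05)
  fit <- fit_dispersion(d, model = "luz_meiboom")
  expect_lt(fit$chi2, 1e-6)
  expect_equal(fit$k_ex, 1500, tolerance = 1e-4)
  expect_equal(unname(fit$per_residue$phi_ppm2), 0.05, tolerance = 1e-4)
  expect_equal(sort(fit$r2_0$r2_0), c(14, 16), tolerance = 1e-5)
  # predict() reproduces the observations
  expect_equal(predict(fit), d$r2eff, tolerance = 1e-6)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-3)
})

test_that("duplicating every curve leaves estimates unchanged and doubles chi2", {
  sim <- gen_dispersion_dataset(dispersion_scenario(
    clusters = list(list(k_ex = 900, model = "luz_meiboom", n_residues = 3,
                         phi_ppm2_range = c(0.02, 0.08))),
    n_decoys = 0, seed = 5))
  fit1 <- fit_dispersion(sim$curves, model = "luz_meiboom")
  dup <- rbind(sim$curves, sim$curves)
  fit2 <- fit_dispersion(dup, model = "luz_meiboom")
  expect_equal(fit2$k_ex, fit1$k_ex, tolerance = 1e-5)
  expect_equal(fit2$per_residue$phi_ppm2, fit1$per_residue$phi_ppm2,
               tolerance = 1e-5)
  expect_equal(fit2$chi2, 2 * fit1$chi2, tolerance = 1e-4)
})

test_that("global cluster fit recovers the generating exchange rate", {
  # 10-residue two-field cluster at the slower wild-type rate
  sim <- gen_dispersion_dataset(dispersion_scenario(
    clusters = list(list(k_ex = 840, model = "carver_richards",
                         n_residues = 10, p_minor = 0.03,
                         dw_ppm_range = c(0.5, 2))),
    n_decoys = 0, seed = 101))
  fit <- fit_dispersion(sim$curves, model = "carver_richards")
  expect_lt(abs(fit$k_ex - 840), 2 * fit$k_ex_se)
  # chi-square behaves: sigma used for generation -> reduced chi2 near 1
  expect_gt(fit$reduced_chi2, 0.5)
  expect_lt(fit$reduced_chi2, 1.5)
})

test_that("recovery is accurate over seeds and errors are calibrated", {
  errs <- c()
  cover <- c()
  for (seed in 1:5) {
    sim <- gen_dispersion_dataset(dispersion_scenario(
      clusters = list(list(k_ex = 2033, model = "carver_richards",
                           n_residues = 6, p_minor = 0.03,
                           dw_ppm_range = c(0.5, 2))),
      n_decoys = 0, seed = seed))
    fit <- fit_dispersion(sim$curves, model = "carver_richards")
    errs <- c(errs, abs(fit$k_ex - 2033) / 2033)
    cover <- c(cover, abs(fit$k_ex - 2033) <= 2 * fit$k_ex_se)
  }
  expect_lt(median(errs), 0.05)
  expect_gte(mean(cover), 0.8)
})

test_that("releasing a shared parameter never increases chi2", {
  sim <- gen_dispersion_dataset(dispersion_scenario(
    clusters = list(list(k_ex = 600, model = "carver_richards",
                         n_residues = 3, p_minor = 0.04,
                         dw_ppm_range = c(0.8, 1.5))),
    n_decoys = 0, seed = 21))
  shared <- fit_dispersion(sim$curves, model = "carver_richards",
                           share_p_minor = TRUE)
  free <- fit_dispersion(sim$curves, model = "carver_richards",
                         share_p_minor = FALSE,
                         kex_starts = shared$k_ex)
  expect_lte(free$chi2, shared$chi2 + 1e-3)
})

test_that("reduced chi-square is chi2 over dof with guarded dof", {
  expect_equal(reduced_chi2(list(chi2 = 50, dof = 25)), 2.0)
  expect_equal(reduced_chi2(list(chi2 = 0, dof = 10)), 0)
  expect_error(reduced_chi2(list(chi2 = 1, dof = 0)), "dof")
})

test_that("F test selects by nested chi-square comparison", {
  d <- noiseless_lm_curves()
  fit <- fit_dispersion(d, model = "luz_meiboom")
  # identical chi2 -> F = 0 -> simple
  fs <- list(chi2 = 10, dof = 20, n_points = fit$n_points, data = fit$data)
  fc <- list(chi2 = 10, dof = 18, n_points = fit$n_points, data = fit$data)
  sel <- f_test_select(fs, fc)
  expect_equal(sel$selected, "simple")
  expect_equal(sel$f, 0)
  # clearly better complex model wins
  fc2 <- list(chi2 = 2, dof = 18, n_points = fit$n_points, data = fit$data)
  expect_equal(f_test_select(fs, fc2)$selected, "complex")
  # different data -> invalid comparison
  d2 <- noiseless_lm_curves(k_ex = 900)
  fd <- list(chi2 = 5, dof = 18, n_points = nrow(d2), data = d2)
  expect_error(f_test_select(fs, fd), "identical data")
  # negative numerator -> simple
  fc3 <- list(chi2 = 11, dof = 18, n_points = fit$n_points, data = fit$data)
  expect_equal(f_test_select(fs, fc3)$selected, "simple")
})

test_that("regime selection favours the matching model on synthetic data", {
  pick_model <- function(sim) {
    lmfit <- fit_dispersion(sim$curves, model = "luz_meiboom")
    crfit <- fit_dispersion(sim$curves, model = "carver_richards")
    f_test_select(lmfit, crfit)$selected
  }
  fast_sel <- vapply(1:10, function(s) pick_model(gen_dispersion_dataset(
    dispersion_scenario(clusters = list(list(
      k_ex = 4000, model = "luz_meiboom", n_residues = 2,
      phi_ppm2_range = c(0.03, 0.1))), n_decoys = 0, seed = s))),
    character(1))
  slow_sel <- vapply(1:10, function(s) pick_model(gen_dispersion_dataset(
    dispersion_scenario(clusters = list(list(
      k_ex = 150, model = "carver_richards", n_residues = 2,
      p_minor = 0.05, dw_ppm_range = c(1.5, 2.5))), n_decoys = 0,
      seed = s))), character(1))
  expect_gte(mean(fast_sel == "simple"), 0.9)   # Luz-Meiboom kept
  expect_gte(mean(slow_sel == "complex"), 0.9)  # Carver-Richards chosen
})

test_that("cluster search prefers the true two-cluster partition", {
  sim <- gen_dispersion_dataset(dispersion_scenario(
    clusters = list(
      list(k_ex = 840, model = "carver_richards", n_residues = 3,
           p_minor = 0.03, dw_ppm_range = c(0.8, 2)),
      list(k_ex = 2033, model = "carver_richards", n_residues = 3,
           p_minor = 0.03, dw_ppm_range = c(0.8, 2))),
    n_decoys = 0, seed = 31))
  members <- sim$truth$members
  two <- list(members[["1"]], members[["2"]])
  one <- list(unlist(members))
  cs <- cluster_search(sim$curves, list(one, two),
                       model = "carver_richards")
  expect_equal(cs$best, 2)
  expect_lt(cs$table$reduced_chi2[cs$table$partition == 2],
            cs$table$reduced_chi2[cs$table$partition == 1])
  # recovered rates near the generating ones
  kx <- sort(vapply(cs$fits[[2]], `[[`, numeric(1), "k_ex"))
  se <- vapply(cs$fits[[2]], `[[`, numeric(1), "k_ex_se")[order(
    vapply(cs$fits[[2]], `[[`, numeric(1), "k_ex"))]
  expect_lt(abs(kx[1] - 840), 2 * se[1])
  expect_lt(abs(kx[2] - 2033), 2 * se[2])
  # identical curves in every partition tie
  d1 <- noiseless_lm_curves()
  cs2 <- cluster_search(d1, list(list("H:R71"), list("H:R71")),
                        model = "luz_meiboom")
  expect_equal(diff(cs2$table$reduced_chi2), 0, tolerance = 1e-6)
})

test_that("dispersion tables round-trip through the delimited-text reader", {
  sim <- gen_dispersion_dataset(dispersion_scenario(
    clusters = list(list(k_ex = 840, model = "luz_meiboom", n_residues = 2)),
    n_decoys = 1, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dispersion_table(sim$curves, path)
  back <- read_dispersion_table(path)
  expect_equal(back$r2eff, sim$curves$r2eff, tolerance = 1e-10)
  expect_equal(back$residue_id, sim$curves$residue_id)
  # comment lines and missing sigma handled
  txt <- c("# a comment", "chain residue aa field_mhz nu_cpmg r2eff",
           "H 5 R 600.13 25 17.1", "H 5 R 600.13 50 16.2",
           "H 5 R 600.13 100 15.4", "H 5 R 600.13 400 15.0")
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(txt, p2)
  d2 <- read_dispersion_table(p2)
  expect_equal(unique(d2$sigma), 0.2)  # configured floor
})
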