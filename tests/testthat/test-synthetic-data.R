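test_that("dispersion generator is exact at zero noise and seed-deterministic", {
  cfg <- dispersion_scenario(
    clusters = list(list(k_ex = 840, model = "carver_richards",
                         n_residues = 2, p_minor = 0.03,
                         dw_ppm_range = c(0.8, 1.5))),
    n_decoys = 0, sigma = 0, seed = 8)
  g <- gen_dispersion_dataset(cfg)
  # zero noise: curves lie exactly on the forward model
  tr <- g$truth$per_residue
  for (i in seq_len(nrow(tr))) {
    rows <- g$curves$residue_id == tr$residue_id[i] &
      g$curves$field_mhz == tr$field_mhz[i]
    mu <- carver_richards_r2eff(
      g$curves$nu_cpmg[rows],
      exchange_params(tr$r2_0[i], tr$k_ex[i], p_minor = tr$p_minor[i],
                      delta_omega_ppm = tr$dw_ppm[i]),
      field_context(tr$field_mhz[i]))
    expect_equal(g$curves$r2eff[rows], mu, tolerance = 1e-12)
  }
  # same seed -> bit-identical outputs
  g2 <- gen_dispersion_dataset(cfg)
  expect_identical(g$curves, g2$curves)
  # different seed differs
  g3 <- gen_dispersion_dataset(dispersion_scenario(
    clusters = cfg$clusters, n_decoys = 0, sigma = 0.3, seed = 9))
  g4 <- gen_dispersion_dataset(dispersion_scenario(
    clusters = cfg$clusters, n_decoys = 0, sigma = 0.3, seed = 10))
  expect_false(identical(g3$curves$r2eff, g4$curves$r2eff))
})

test_that("decoy residues are always removed by the exclusion rule", {
  for (seed in 1:5) {
    g <- gen_dispersion_dataset(dispersion_scenario(seed = seed))
    decoys <- unique(g$truth$per_residue$residue_id[
      g$truth$per_residue$model == "decoy"])
    ex <- exclude_flat_curves(g$curves)
    expect_true(all(decoys %in% unique(ex$excluded$residue_id)))
    # and the genuinely dispersive cluster members are kept
    members <- unlist(g$truth$members)
    expect_true(all(members %in% unique(ex$kept$residue_id)))
  }
})

test_that("ITC generator matches the stated protocol and conserves heat", {
  g <- gen_itc_experiment(itc_scenario(seed = 3))
  expect_length(g$experiment$heats, 25)
  expect_equal(g$experiment$injection_volumes, rep(10e-6, 25))
  expect_equal(g$experiment$cell_concentration, 2e-6)
  expect_equal(g$experiment$syringe_concentration, 30e-6)
  # saturation: total heat ~ dH x limiting moles (K_A = 2e9 saturates fully)
  lim_mol <- 2e-6 * 1.4e-3
  expect_equal(sum(g$experiment$heats), g$truth$delta_h * 1000 * lim_mol,
               tolerance = 0.05)
  # round trip at zero noise
  g0 <- gen_itc_experiment(itc_scenario(
    ka = 5e6, delta_h = -60, cell_concentration = 2e-5,
    syringe_concentration = 3e-4, noise_sd = 0, seed = 4))
  f <- fit_itc(g0$experiment)
  expect_equal(f$ka, 5e6, tolerance = 0.02)
  expect_equal(f$delta_h, -60, tolerance = 0.005)
  expect_equal(f$n, 1, tolerance = 0.005)
  # determinism
  expect_identical(gen_itc_experiment(itc_scenario(seed = 3))$experiment$heats,
                   g$experiment$heats)
})

test_that("annotation fixtures encode their expected selection outcome", {
  fx <- gen_annotation_fixture(annotation_scenario(seed = 2))
  expect_equal(nrow(fx$annotations), 32)
  expect_length(fx$expected, 8)
  expect_true(all(fx$annotations$has_dispersion))
  # expected set equals independent enumeration
  expect_equal(fx$expected, brute_force_select(fx$annotations))
  # a CDR-located His at L:34 is present and never expected
  expect_true("L:H34" %in% fx$annotations$residue_id)
  expect_false("L:H34" %in% fx$expected)
  # all-small composition yields an empty expected set
  fx0 <- gen_annotation_fixture(annotation_scenario(
    n_dispersive = 10, n_pass = 0, n_cdr = 3, n_small = 4, seed = 3))
  expect_length(fx0$expected, 0)
  ann_gly <- fx$annotations
  ann_gly$aa <- "G"
  expect_equal(nrow(select_candidates(ann_gly)$selected), 0)
  # impossible compositions are rejected
  expect_error(gen_annotation_fixture(annotation_scenario(
    n_dispersive = 5, n_pass = 4, n_cdr = 3, n_small = 3)), "impossible")
})

test_that("snapshot ensembles reflect amplitude and the designed median shift", {
  # zero amplitude -> all frames identical
  g0 <- gen_snapshot_ensemble(ensemble_scenario(amplitude = 0, n_frames = 5,
                                                seed = 1))
  expect_equal(g0$ensemble$coords[, , 1], g0$ensemble$coords[, , 5])
  # designed 1.1 A shift in a pair distance is recovered at n = 130
  base_a <- synthetic_minifold()
  base_b <- synthetic_minifold()
  ca_ix <- which(base_b$atoms$chain == "H" & base_b$atoms$residue == 10 &
                 base_b$atoms$atom == "CA")
  ca_jx <- which(base_b$atoms$chain == "H" & base_b$atoms$residue == 3 &
                 base_b$atoms$atom == "CA")
  dir <- base_b$xyz[ca_ix, ] - base_b$xyz[ca_jx, ]
  dir <- dir / sqrt(sum(dir^2))
  move <- base_b$atoms$chain == "H" & base_b$atoms$residue == 10
  base_b$xyz[move, ] <- sweep(base_b$xyz[move, ], 2, 1.1 * dir, `-`)
  ga <- gen_snapshot_ensemble(ensemble_scenario(base = base_a, seed = 5))
  gb <- gen_snapshot_ensemble(ensemble_scenario(base = base_b, seed = 6))
  da <- ca_distance_series(ga$ensemble, "H:3", "H:10")
  db <- ca_distance_series(gb$ensemble, "H:3", "H:10")
  cmpr <- compare_distance_distributions(da, db)
  expect_length(da, 130)
  expect_equal(cmpr$median_shift, 1.1, tolerance = 0.2)
  expect_lt(cmpr$p_value, 1e-6)
  # seed determinism
  ga2 <- gen_snapshot_ensemble(ensemble_scenario(base = base_a, seed = 5))
  expect_identical(ga$ensemble$coords, ga2$ensemble$coords)
})

test_that("generators restore the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_itc_experiment(itc_scenario(seed = 1)))
  invisible(gen_annotation_fixture(annotation_scenario(seed = 1)))
  expect_identical(.Random.seed, before)
})
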