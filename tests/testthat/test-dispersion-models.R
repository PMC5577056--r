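f600 <- field_context(600.13)
f750 <- field_context(750.13)
NU <- c(25, 50, 75, 100, 150, 200, 300, 400, 500, 650, 800, 1000)

test_that("intensity-to-R2eff conversion follows the constant-time relation", {
  expect_equal(r2eff_from_intensity(3, 3, 0.04), 0)
  expect_equal(r2eff_from_intensity(exp(-1), 1, 0.04), 25)
  expect_equal(r2eff_from_intensity(0.5, 1, 0.02), log(2) / 0.02,
               tolerance = 1e-12)
  # invariant under common intensity scaling
  expect_equal(r2eff_from_intensity(0.4 * 7, 1 * 7, 0.05),
               r2eff_from_intensity(0.4, 1, 0.05))
  expect_error(r2eff_from_intensity(-1, 1, 0.04), "positive")
  expect_error(r2eff_from_intensity(1, 0, 0.04), "positive")
})

test_that("Luz-Meiboom reduces to R2_0 without exchange and at fast pulsing", {
  p0 <- exchange_params(12, 1000, phi_ppm2 = 0)
  expect_equal(luz_meiboom_r2eff(NU, p0, f600), rep(12, length(NU)))
  # k_ex -> Inf limit
  pfast <- exchange_params(12, 1e9, phi_ppm2 = 0.05)
  expect_equal(luz_meiboom_r2eff(NU, pfast, f600), rep(12, length(NU)),
               tolerance = 1e-4)
  # known limits in nu
  p <- exchange_params(12, 1500, phi_ppm2 = 0.05)
  phi_rad <- 0.05 * (2 * pi * 600.13 * NITROGEN15_RATIO)^2
  expect_equal(luz_meiboom_r2eff(1e-4, p, f600), 12 + phi_rad / 1500,
               tolerance = 1e-6)
  expect_equal(luz_meiboom_r2eff(1e7, p, f600), 12, tolerance = 1e-3)
  expect_error(luz_meiboom_r2eff(NU, exchange_params(12, 100), f600),
               "phi_ppm2")
})

test_that("Carver-Richards degenerates to R2_0 for identical or absent minor state", {
  pd <- exchange_params(9, 700, p_minor = 0.04, delta_omega_ppm = 0)
  expect_equal(carver_richards_r2eff(NU, pd, f600), rep(9, length(NU)),
               tolerance = 1e-9)
  p0 <- exchange_params(9, 700, p_minor = 0, delta_omega_ppm = 1.5)
  expect_equal(carver_richards_r2eff(NU, p0, f600), rep(9, length(NU)),
               tolerance = 1e-9)
})

test_that("both closed forms agree with the Bloch-McConnell propagator on a spanning grid", {
  # 100 parameter sets across slow/intermediate/fast exchange, realistic
  # amplitudes; long relaxation period isolates the asymptotic rate that the
  # closed forms describe
  set.seed(42)
  worst_cr <- 0
  worst_lm <- 0
  for (i in 1:100) {
    regime <- sample(c("slow", "int", "fast"), 1)
    kex <- switch(regime,
                  slow = exp(runif(1, log(50), log(300))),
                  int = exp(runif(1, log(300), log(2000))),
                  fast = exp(runif(1, log(2000), log(20000))))
    pb <- runif(1, 0.01, 0.05)
    dd <- runif(1, 0.3, 2)
    pars <- exchange_params(0, kex, p_minor = pb, delta_omega_ppm = dd)
    bm <- bloch_mcconnell_r2eff(NU, pars, f600, relaxation_period = 1.0)
    worst_cr <- max(worst_cr,
                    max(abs(bm - carver_richards_r2eff(NU, pars, f600))))
    dw_rad <- dd * 2 * pi * 600.13 * NITROGEN15_RATIO
    if (kex / dw_rad >= 20) {
      plm <- exchange_params(0, kex, phi_ppm2 = pb * (1 - pb) * dd^2)
      worst_lm <- max(worst_lm,
                      max(abs(bm - luz_meiboom_r2eff(NU, plm, f600))))
    }
  }
  expect_lt(worst_cr, 0.05)
  expect_lt(worst_lm, 0.05)
})

test_that("fast-exchange consistency: CR and LM agree when k_ex >> dw", {
  set.seed(7)
  for (i in 1:20) {
    dd <- runif(1, 0.3, 1.5)
    dw_rad <- dd * 2 * pi * 600.13 * NITROGEN15_RATIO
    kex <- dw_rad * runif(1, 20, 60)
    pb <- runif(1, 0.01, 0.05)
    cr <- carver_richards_r2eff(
      NU, exchange_params(10, kex, p_minor = pb, delta_omega_ppm = dd), f600)
    lm <- luz_meiboom_r2eff(
      NU, exchange_params(10, kex, phi_ppm2 = pb * (1 - pb) * dd^2), f600)
    expect_lt(max(abs(cr - lm)), 0.1)
  }
})

test_that("R2eff is non-increasing in CPMG frequency and bounded below by R2_0", {
  # outside deep slow exchange (k_ex well below dw, where CPMG dispersion
  # profiles genuinely oscillate), both closed forms decay monotonically
  set.seed(11)
  nu_dense <- seq(25, 2000, by = 25)
  for (i in 1:40) {
    kex <- exp(runif(1, log(80), log(8000)))
    pb <- runif(1, 0.005, 0.05)
    dd <- runif(1, 0.2, 2.5)
    pars <- exchange_params(8, kex, p_minor = pb, delta_omega_ppm = dd,
                            phi_ppm2 = pb * (1 - pb) * dd^2)
    vlm <- luz_meiboom_r2eff(nu_dense, pars, f600)
    expect_true(all(diff(vlm) <= 1e-6))
    expect_true(all(vlm >= 8 - 1e-6))
    dw_rad <- dd * 2 * pi * 600.13 * NITROGEN15_RATIO
    vcr <- carver_richards_r2eff(nu_dense, pars, f600)
    expect_true(all(vcr >= 8 - 1e-6))
    if (kex / dw_rad >= 0.5) expect_true(all(diff(vcr) <= 1e-6))
  }
})

test_that("propagator obeys no-exchange, shift-sign and slow-exchange limits", {
  # no minor state -> pure R2_0
  p0 <- exchange_params(11, 1, p_minor = 0, delta_omega_ppm = 1.4)
  expect_equal(bloch_mcconnell_r2eff(c(25, 100, 500), p0, f600),
               rep(11, 3), tolerance = 1e-9)
  # invariant under sign flip of the shift difference
  pa <- exchange_params(10, 500, p_minor = 0.04, delta_omega_ppm = 1.1)
  pb <- exchange_params(10, 500, p_minor = 0.04, delta_omega_ppm = -1.1)
  expect_equal(bloch_mcconnell_r2eff(NU, pa, f600),
               bloch_mcconnell_r2eff(NU, pb, f600), tolerance = 1e-10)
  # slow exchange: R_ex at slow pulsing approaches p_minor * k_ex
  ps <- exchange_params(5, 100, p_minor = 0.02, delta_omega_ppm = 3)
  rex_lo <- bloch_mcconnell_r2eff(12.5, ps, f600,
                                  relaxation_period = 0.08) - 5
  expect_equal(rex_lo, 0.02 * 100, tolerance = 0.05)
})

test_that("field scaling: one ppm-level parameter set predicts both fields", {
  p <- exchange_params(0, 1500, phi_ppm2 = 0.06)
  r600 <- luz_meiboom_r2eff(NU, p, f600)
  r750 <- luz_meiboom_r2eff(NU, p, f750)
  # amplitude scales with B0^2
  expect_equal(r750 / r600, rep((750.13 / 600.13)^2, length(NU)),
               tolerance = 1e-10)
})

test_that("R_ex amplitude matches its analytic and numerical definitions", {
  # fast model: exactly Phi_rad / k_ex
  w1 <- 2 * pi * 600.13 * NITROGEN15_RATIO
  phi_ppm2 <- 2000 / w1^2
  p <- exchange_params(15, 1000, phi_ppm2 = phi_ppm2)
  expect_equal(rex_amplitude(p, f600, "luz_meiboom"), 2.0, tolerance = 1e-12)
  expect_equal(rex_amplitude(exchange_params(15, 1000, phi_ppm2 = 0), f600,
                             "luz_meiboom"), 0)
  # Carver-Richards: analytic limit equals evaluation at extreme frequencies
  pc <- exchange_params(15, 840, p_minor = 0.03, delta_omega_ppm = 1.2)
  num <- carver_richards_r2eff(10, pc, f600) -
    carver_richards_r2eff(1e4, pc, f600)
  expect_equal(rex_amplitude(pc, f600, "carver_richards"), num,
               tolerance = 0.01 * num)
  expect_gte(rex_amplitude(pc, f600, "carver_richards"), 0)
})

test_that("constructors validate their invariants", {
  expect_error(field_context(-600), "> 0")
  expect_error(field_context(600, nucleus_ratio = 2), "in \\(0, 1\\]")
  expect_error(exchange_params(-1, 100), ">= 0")
  expect_error(exchange_params(1, 0), "> 0")
  expect_error(exchange_params(1, 100, p_minor = 0.7), "p_minor")
  expect_error(exchange_params(1, 100, phi_ppm2 = -1), "phi_ppm2")
  expect_error(cpmg_grid(c(50, 25), 0.04), "increasing")
  expect_error(cpmg_grid(c(25, 50), -1), "> 0")
  g <- cpmg_grid(c(25, 50), 0.04)
  expect_s3_class(g, "cpmg_grid")
})
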