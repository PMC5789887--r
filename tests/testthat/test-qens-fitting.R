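test_that("per-Q decomposition recovers a noiseless two-Lorentzian spectrum", {
  g <- default_energy_grid()
  k <- gaussian_resolution_kernel(g)
  mix <- two_lorentzian_model(0.6, 0.01, 0.14)   # Gamma_tot = 0.15
  y <- convolved_mixture(mix, g, k)
  sp <- qens_spectrum(1.0, g, y, rep(max(y) * 1e-3, length(y)))
  f <- fit_per_q(sp, k, "fluid", n_starts = 4, seed = 2)
  expect_equal(f$A, 0.6, tolerance = 1e-3)
  expect_equal(f$gamma_lat, 0.01, tolerance = 1e-3)
  expect_equal(f$gamma_tot, 0.15, tolerance = 1e-3)
  expect_equal(f$scale, 1, tolerance = 1e-3)
  expect_gte(f$gamma_tot, f$gamma_lat)   # ordering by construction
})

test_that("per-Q coagel fits use a resolution-shaped elastic line", {
  g <- default_energy_grid()
  k <- gaussian_resolution_kernel(g)
  mix <- two_lorentzian_model(0.8, 0, 0.05)
  y <- 2.5 * convolved_mixture(mix, g, k)
  sp <- qens_spectrum(0.7, g, y, rep(max(y) * 1e-3, length(y)))
  f <- fit_per_q(sp, k, "coagel", n_starts = 4, seed = 3)
  expect_equal(f$A, 0.8, tolerance = 1e-3)
  expect_equal(f$gamma_int, 0.05, tolerance = 1e-3)
  expect_equal(f$gamma_lat, 0)
  expect_equal(f$scale, 2.5, tolerance = 1e-2)
})

test_that("a fully elastic spectrum flags the internal width as unidentifiable", {
  g <- default_energy_grid()
  k <- gaussian_resolution_kernel(g)
  mix <- two_lorentzian_model(1, 0.02, 0)  # A = 1: single Lorentzian
  y <- convolved_mixture(mix, g, k)
  sp <- qens_spectrum(1.0, g, y, rep(max(y) * 1e-3, length(y)))
  f <- fit_per_q(sp, k, "fluid", n_starts = 4, seed = 4)
  expect_equal(f$gamma_lat, 0.02, tolerance = 5e-3)
  expect_match(paste(f$flags, collapse = ";"), "unidentifiable")
})

test_that("per-Q parameter pulls are calibrated under Poisson noise", {
  g <- default_energy_grid()
  k <- gaussian_resolution_kernel(g)
  pulls <- t(vapply(1:50, function(s) {
    ds <- generate_qens_dataset(
      "fluid", fluid_345K_fixture(), lateral_model(3.5e-6), q = 1.0,
      noise = "poisson", seed = 600 + s)
    f <- fit_per_q(ds$spectra[[1]], k, "fluid", n_starts = 2, seed = s)
    truthA <- eisf_fluid(1.0, fluid_345K_fixture())
    truthgl <- gamma_lateral(1.0, lateral_model(3.5e-6))
    c((f$A - truthA) / f$A_se, (f$gamma_lat - truthgl) / f$gamma_lat_se)
  }, numeric(2)))
  expect_lt(abs(mean(pulls[, 1])), 0.3 + 3 / sqrt(50))
  expect_lt(abs(mean(pulls[, 2])), 0.3 + 3 / sqrt(50))
})

test_that("EISF fits invert noiseless model curves", {
  qv <- instrument_q()
  p <- gel_coagel_params(p_x = 0.15, a = 1.7, tau = 1, tau_MG = 1)
  A <- eisf_gel_coagel(qv, p)
  f <- fit_eisf(qv, A, phase = "coagel", n_starts = 4, seed = 1)
  expect_equal(f$p_x, 0.15, tolerance = 1e-3)
  expect_equal(f$a, 1.7, tolerance = 1e-3)
  # flat EISF: p_x at the zero boundary, radius flagged unidentifiable
  f1 <- fit_eisf(qv, rep(1, length(qv)), phase = "gel", n_starts = 4, seed = 2)
  expect_lt(f1$p_x, 1e-3)
  expect_match(paste(f1$flags, collapse = ";"), "unidentifiable")
  expect_error(fit_eisf(qv[1:3], A[1:3], phase = "coagel"), "at least 4")
})

test_that("fluid EISF fit recovers the confinement radii under 2% noise", {
  qv <- instrument_q()
  p <- fluid_params(R_min = 0.3, R_max = 3.3, D_min = 1, D_max = 1, tau_MG = 1)
  A0 <- eisf_fluid(qv, p)
  recov <- vapply(1:50, function(s) {
    set.seed(s)
    A <- A0 * (1 + stats::rnorm(length(qv), 0, 0.02))
    fit_eisf(qv, A, sigma = 0.02 * A0, phase = "fluid",
             n_starts = 4, seed = s)$R_max
  }, numeric(1))
  expect_lt(abs(stats::median(recov) / 3.3 - 1), 0.05)
})

test_that("HWHM fits recover the generating rates without noise", {
  qv <- instrument_q()
  pg <- gel_fixture()
  gi <- model_hwhm(qv, "gel", pg)
  hw <- fit_hwhm_internal(qv, gi, phase = "gel",
                          geometry = list(p_x = 0.64, a = 1.8),
                          n_starts = 6, seed = 2)
  expect_equal(hw$D_r_per_s, 6.8e10, tolerance = 0.02)
  expect_equal(hw$tau_MG, 5.2, tolerance = 0.02)
  pf <- fluid_345K_fixture()
  gif <- model_hwhm(qv, "fluid", pf)
  hwf <- fit_hwhm_internal(qv, gif, phase = "fluid",
                           geometry = list(R_min = 0.3, R_max = 5.4),
                           n_starts = 6, seed = 3)
  expect_equal(hwf$D_max_cm2s, 26.1e-6, tolerance = 0.02)
  expect_equal(hwf$D_min_cm2s, 0.6e-6, tolerance = 0.05)
  expect_equal(hwf$tau_MG, 2.6, tolerance = 0.02)
})

test_that("Fickian fit inverts the unit chain exactly", {
  qv <- c(0.6, 1.0, 1.5, 1.8)
  f <- fit_fickian(qv, 0.65821 * 0.015 * qv^2)
  expect_equal(f$D_lat_cm2s, 1.5e-6, tolerance = 1e-12)
  expect_equal(fit_fickian(qv, rep(0, 4))$D_lat_cm2s, 0)
  expect_error(fit_fickian(qv, -0.01 * qv^2), "negative")
  expect_error(fit_fickian(qv[1:2], qv[1:2]), "at least 3")
  # unbiased under 5% noise
  d <- vapply(1:200, function(s) {
    set.seed(s)
    fit_fickian(qv, 0.65821 * 0.015 * qv^2 *
                  (1 + stats::rnorm(4, 0, 0.05)))$D_lat_cm2s
  }, numeric(1))
  se <- stats::sd(d) / sqrt(200)
  expect_lt(abs(mean(d) - 1.5e-6), 2 * se)
})

test_that("Arrhenius fit matches the closed-form two-point solution", {
  ar <- fit_arrhenius(c(315, 345), c(1.5e-6, 3.5e-6))
  slope <- log(3.5 / 1.5) / (1 / 345 - 1 / 315)
  expect_equal(ar$E_a_kcal_mol, -slope * 1.98720e-3, tolerance = 1e-12)
  expect_equal(ar$E_a_kcal_mol, 6.10, tolerance = 1e-2)
  # equal D at two temperatures: E_a = 0
  expect_equal(fit_arrhenius(c(300, 330), c(1e-6, 1e-6))$E_a_kcal_mol, 0)
  # exact Arrhenius data at three temperatures inverts to machine precision
  Ea <- 6.12; D0 <- 2e-4
  T3 <- c(315, 330, 345)
  D3 <- D0 * exp(-Ea / (1.98720e-3 * T3))
  ar3 <- fit_arrhenius(T3, D3)
  expect_equal(ar3$E_a_kcal_mol, 6.12, tolerance = 1e-6)
  expect_equal(ar3$D_0_cm2s, D0, tolerance = 1e-6)
  expect_error(fit_arrhenius(c(300, 330), c(1e-6, -1e-6)), "positive")
  expect_error(fit_arrhenius(300, 1e-6), "at least 2")
})
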