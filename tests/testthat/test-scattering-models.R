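test_that("lorentzian is the unit-area closed form", {
  expect_equal(lorentzian(0, 0.1), 1 / (0.1 * pi))
  expect_equal(lorentzian(0.1, 0.1), (1 / pi) * (0.1 / 0.02))
  expect_equal(lorentzian(0.3, 0.05), lorentzian(-0.3, 0.05))
  num <- stats::integrate(lorentzian, -Inf, Inf, gamma = 0.1)$value
  expect_equal(num, 1, tolerance = 1e-6)
  expect_error(lorentzian(0, 0), "positive")
  expect_error(lorentzian(0, -1), "positive")
})

test_that("jump-rotation structure factors obey the sum rule and limits", {
  B <- jump_rotation_structure_factors(0, 12)
  expect_equal(B[1], 1)
  expect_equal(B[-1], rep(0, 11), tolerance = 1e-12)
  for (qa in c(0.3, 1.0, 2.0, 5.0)) {
    for (ns in c(3, 6, 12)) {
      B <- jump_rotation_structure_factors(qa, ns)
      expect_equal(sum(B), 1, tolerance = 1e-12)
    }
  }
  # large Qa: only the i = N_s term survives, B_0 -> 1/N_s
  B <- jump_rotation_structure_factors(5000, 12)
  expect_equal(B[1], 1 / 12, tolerance = 1e-3)
  expect_error(jump_rotation_structure_factors(1, 1), "at least 2")
})

test_that("uniaxial rotation law conserves weight with closed-form widths", {
  p <- gel_coagel_params(p_x = 1, a = 1.7, tau = 2, tau_MG = 1, N_s = 12)
  m0 <- uniaxial_rotation_model(0, p)
  expect_equal(m0$elastic, 1)
  m <- uniaxial_rotation_model(1.5 / p$a, p)  # Qa = 1.5
  expect_equal(mixture_weight(m), 1, tolerance = 1e-12)
  # narrowest line: hbar * 2 sin^2(pi/12) / tau
  expect_equal(min(m$gammas), 0.65821 * 2 * sin(pi / 12)^2 / 2,
               tolerance = 1e-12)
  expect_equal(min(m$gammas), 0.0441, tolerance = 1e-3)
})

test_that("methyl 3-fold law has the closed-form elastic fraction and width", {
  m <- methyl_3fold_model(0, b = 1.8, tau_MG = 6.7)
  expect_equal(m$elastic, 1)
  m <- methyl_3fold_model(1.0, b = 1.8, tau_MG = 6.7)
  expect_equal(m$gammas, 3 * 0.65821 / 6.7)
  expect_equal(m$gammas, 0.2947, tolerance = 1e-3)
  expect_equal(mixture_weight(m), 1)
  # high-Q limit of the elastic fraction is 1/3
  m <- methyl_3fold_model(5000, b = 1.8, tau_MG = 6.7)
  expect_equal(m$elastic, 1 / 3, tolerance = 1e-3)
})

test_that("sphere eigenvalues match the brute-force sign-scan oracle", {
  eig <- sphere_eigenvalues(6, 6)
  expect_equal(eig$x[2, 1], 2.0816, tolerance = 1e-3)
  expect_equal(eig$x[1, 1], 4.4934, tolerance = 1e-3)
  expect_true(all(eig$x > 0))
  expect_true(all(apply(eig$x, 1, function(r) all(diff(r) > 0))))
  for (l in c(0, 1, 3, 5)) {
    oracle <- oracle_sphere_eigenvalues(l, 4)
    expect_equal(eig$x[l + 1, 1:4], oracle, tolerance = 1e-6)
  }
})

test_that("confined-sphere law: completeness, Q->0 width, free-diffusion limit", {
  eig <- sphere_eigenvalues(20, 20)
  sf <- sphere_structure_factors(2.0, eig)
  expect_equal(sf$elastic + sum(sf$weights), 1, tolerance = 1e-3)
  m0 <- confined_sphere_model(1e-4, R = 3, D = 0.1, eig)
  expect_equal(m0$elastic, 1, tolerance = 1e-6)
  # Q->0 HWHM plateau: (x_1^1)^2 hbar D / R^2 = 4.333 hbar D / R^2
  hw0 <- mixture_hwhm(confined_sphere_model(0.01, R = 3, D = 0.1, eig))
  expect_equal(hw0, 4.333 * 0.65821 * 0.1 / 9, tolerance = 0.01)
  # crossover: below the confinement length the width sits on the plateau
  # (above hbar D Q^2); beyond it, it approaches the free-diffusion width
  # monotonically from below as QR grows (QR within truncation validity)
  qs <- c(1, 4, 6, 9) / 3
  hw <- vapply(qs, function(q)
    mixture_hwhm(confined_sphere_model(q, R = 3, D = 0.1, eig)), numeric(1))
  free <- 0.65821 * 0.1 * qs^2
  ratio <- hw / free
  expect_gt(ratio[1], 1)                 # plateau regime, QR = 1
  expect_true(all(ratio[-1] < 1))        # QR = 4, 6, 9
  expect_true(all(diff(ratio[-1]) > 0))
  expect_error(confined_sphere_model(1, R = 3, D = 0), "D > 0")
})

test_that("EISFs are 1 at Q = 0, bounded, with the printed high-Q limits", {
  pc <- coagel_fixture()
  expect_equal(eisf_gel_coagel(0, pc), 1)
  qgrid <- seq(0, 5, by = 0.1)
  A <- eisf_gel_coagel(qgrid, pc)
  expect_true(all(A >= 0 & A <= 1))
  # term-by-term high-Q limit: P_h/3 + P_t (1 - p_x) + P_t p_x / N_s
  lim <- 0.025 + 0.925 * 0.85 + 0.925 * 0.15 / 12
  expect_equal(lim, 0.8228, tolerance = 1e-4)
  expect_equal(eisf_gel_coagel(60, pc), lim, tolerance = 5e-3)
  # no mobile atoms: A == 1 at every Q
  p0 <- gel_coagel_params(p_x = 0, a = 1.7, tau = 1, tau_MG = 1,
                          P_h = 0, P_t = 1)
  expect_equal(eisf_gel_coagel(c(0.5, 1.2, 3), p0), rep(1, 3))

  pf <- fluid_345K_fixture()
  expect_equal(eisf_fluid(0, pf), 1)
  Af <- eisf_fluid(qgrid, pf)
  expect_true(all(Af >= 0 & Af <= 1))
  expect_lt(abs(eisf_fluid(300, pf) - 0.075 / 3), 2e-4)
  # degenerate R distribution collapses to the single-sphere EISF
  pd <- fluid_params(2, 2, 0.1, 0.1, tau_MG = 1)
  q <- 1.3
  single <- (3 * sph_bessel_j(1, q * 2) / (q * 2))^2
  expect_equal(eisf_fluid(q, pd),
               pd$P_h / 3 * (1 + 2 * sph_bessel_j(0, q * 1.8)) +
                 pd$P_t * single, tolerance = 1e-12)
})

test_that("composite internal laws conserve weight and match their EISF", {
  pc <- gel_fixture()
  pf <- fluid_345K_fixture()
  for (q in c(0.5, 1.0, 1.8)) {
    mg <- internal_model(q, "gel", pc)
    expect_equal(mg$elastic, eisf_gel_coagel(q, pc))
    expect_equal(mixture_weight(mg), 1, tolerance = 1e-6)
    mf <- internal_model(q, "fluid", pf)
    expect_equal(mf$elastic, eisf_fluid(q, pf))
    expect_equal(mixture_weight(mf), 1, tolerance = 2e-3)
  }
  expect_error(internal_model(1, "fluid", pc), "fluid_params")
  expect_error(internal_model(1, "gel", pf), "gel_coagel_params")
})

test_that("numerical model HWHM agrees with the dense-grid oracle", {
  # single Lorentzian: HWHM is the width itself
  m1 <- lorentzian_mixture(0, 1, 0.2)
  expect_equal(mixture_hwhm(m1), 0.2, tolerance = 1e-9)
  # equal-weight mix of two widths vs the independent dense-grid oracle
  m2 <- lorentzian_mixture(0, c(0.5, 0.5), c(0.1, 0.3))
  expect_equal(mixture_hwhm(m2), oracle_hwhm(m2), tolerance = 1e-4)
  # 20 random mixtures, 1% agreement
  set.seed(42)
  for (k in 1:20) {
    n <- sample(2:6, 1)
    m <- lorentzian_mixture(0, stats::runif(n), exp(stats::runif(n, -4, 0)))
    expect_equal(mixture_hwhm(m), oracle_hwhm(m), tolerance = 0.01)
  }
  # confined motion: HWHM flattens to a finite nonzero value as Q -> 0
  pf <- fluid_345K_fixture()
  hw <- model_hwhm(c(0.02, 0.2, 1.0), "fluid", pf)
  expect_gt(hw[1], 0.001)
  expect_lt(abs(hw[2] - hw[1]) / hw[1], 0.05)
  expect_gt(hw[3], hw[2])
})

test_that("bilayer law: width additivity, lateral unit chain, D_lat = 0 limit", {
  lat <- lateral_model(1.5e-6)
  expect_equal(gamma_lateral(1.0, lat), 0.65821 * 0.015, tolerance = 1e-12)
  expect_equal(gamma_lateral(1.0, lat), 9.87e-3, tolerance = 1e-3)
  pf <- fluid_345K_fixture()
  m <- bilayer_model(1.0, lat, pf, "fluid")
  gl <- gamma_lateral(1.0, lat)
  gi <- model_hwhm(1.0, "fluid", pf)
  expect_equal(m$elastic, 0)
  expect_equal(sort(m$gammas), sort(c(gl, gl + gi)), tolerance = 1e-12)
  expect_equal(m$weights[1], eisf_fluid(1.0, pf))
  # D_lat = 0 reduces to elastic line + single internal Lorentzian
  m0 <- bilayer_model(1.0, lateral_model(0), pf, "fluid")
  expect_equal(m0$elastic, eisf_fluid(1.0, pf))
  expect_equal(m0$gammas, gi, tolerance = 1e-12)
  # full form: every internal component is shifted by Gamma_lat
  mfull <- bilayer_model(1.0, lat, pf, "fluid", form = "full")
  expect_equal(min(mfull$gammas), gl, tolerance = 1e-12)
  expect_equal(mixture_weight(mfull), 1, tolerance = 2e-3)
})
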