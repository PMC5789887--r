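test_that("generators are deterministic under seed and leave the RNG alone", {
  p <- fluid_345K_fixture()
  lat <- lateral_model(3.5e-6)
  d1 <- generate_qens_dataset("fluid", p, lat, q = c(0.7, 1.3), seed = 42)
  d2 <- generate_qens_dataset("fluid", p, lat, q = c(0.7, 1.3), seed = 42)
  expect_identical(d1$spectra, d2$spectra)
  d3 <- generate_qens_dataset("fluid", p, lat, q = c(0.7, 1.3), seed = 43)
  expect_false(identical(d1$spectra[[1]]$intensity,
                         d3$spectra[[1]]$intensity))
  # caller's RNG stream is not consumed
  set.seed(99); before <- stats::runif(3)
  set.seed(99); invisible(generate_qens_dataset("fluid", p, lat, q = 0.7,
                                                seed = 1))
  expect_identical(stats::runif(3), before)
})

test_that("noise = none reproduces the convolved model to 1e-12", {
  p <- coagel_fixture()
  ds <- generate_qens_dataset("coagel", p, q = 1.0, noise = "none", seed = 1)
  sp <- ds$spectra[[1]]
  mix <- bilayer_model(1.0, NULL, p, "coagel")
  y <- convolved_mixture(mix, sp$energies, ds$resolution)
  y <- y * max(sp$intensity) / max(y)
  expect_equal(sp$intensity, y, tolerance = 1e-12)
})

test_that("Poisson noise has the right first moment", {
  p <- coagel_fixture()
  ds0 <- generate_qens_dataset("coagel", p, q = 1.0, noise = "none",
                               peak_counts = 1e4, seed = 1)
  mu <- ds0$spectra[[1]]$intensity
  bins <- c(100, 400, 651, 900, 1200)
  reps <- vapply(1:200, function(s)
    generate_qens_dataset("coagel", p, q = 1.0, noise = "poisson",
                          peak_counts = 1e4, seed = s)$spectra[[1]]$intensity[bins],
    numeric(length(bins)))
  m <- rowMeans(reps)
  se <- sqrt(mu[bins] / 200)   # Poisson variance = mean
  expect_true(all(abs(m - mu[bins]) < 3 * se))
})

test_that("elastic-scan generator matches the Debye-Waller closed form", {
  sc <- generate_elastic_scan(data.frame(T_K = 300, u2 = 0.5), q = 1,
                              noise_frac = 0, seed = 1)
  expect_equal(sc$I_el[sc$T_K == 300], exp(-0.5 / 6), tolerance = 1e-12)
  expect_equal(exp(-0.5 / 6), 0.9200, tolerance = 1e-4)
  # u2 = 0 gives flat unit ratios
  sc0 <- generate_elastic_scan(data.frame(T_K = c(300, 320), u2 = 0),
                               q = c(0.5, 1.0), seed = 1)
  expect_equal(sc0$I_el, rep(1, nrow(sc0)))
})

test_that("the confined walker never leaves its sphere", {
  tb <- generate_trajectory(n_particles = 50, n_frames = 400, dt = 0.5,
                            D_lat = 0, R = 2.5, D_sphere = 0.3, seed = 6)
  r <- sqrt(tb$positions[, , 1]^2 + tb$positions[, , 2]^2 +
              tb$positions[, , 3]^2)
  expect_lte(max(r), 2.5)
  # and its long-run radial distribution fills the sphere (not stuck)
  expect_gt(mean(r[-(1:50), ]), 1.5)
})

test_that("COM mean-squared displacement grows as 4 D t (2D Brownian)", {
  tb <- generate_trajectory(n_particles = 1000, n_frames = 60, dt = 0.5,
                            D_lat = 0.2, R = 0, D_sphere = 0, seed = 8)
  lag <- 40
  d <- tb$positions[1 + lag, , 1:2] - tb$positions[1, , 1:2]
  msd <- rowSums(d^2)
  se <- stats::sd(msd) / sqrt(length(msd))
  expect_lt(abs(mean(msd) - 4 * 0.2 * lag * 0.5), 3 * se)
})

test_that("static generators produce unit ISF", {
  tb <- generate_trajectory(n_particles = 30, n_frames = 10, dt = 1,
                            D_lat = 0, R = 0, D_sphere = 0, jump_dist = 0,
                            seed = 3)
  isf <- compute_isf(tb, q = 1.2, max_lag = 5)
  expect_equal(isf$isf, rep(1, 6), tolerance = 1e-12)
})

test_that("chain generator honours its gauche fraction and records truth", {
  tb0 <- generate_chain_conformations(n_chains = 5, gauche_fraction = 0,
                                      seed = 1)
  expect_equal(gauche_trans_ratio(tb0, frames = 1)$ratio, 0)
  # expected gauche/trans ratio g/(1-g) = 0.24  =>  g = 0.24/1.24
  g <- 0.24 / 1.24
  tb <- generate_chain_conformations(n_chains = 700, gauche_fraction = g,
                                     seed = 2)
  gt <- gauche_trans_ratio(tb, frames = 1)
  truth <- attr(tb, "truth")$states
  n <- length(truth)
  se_ratio <- sqrt(g * (1 - g) / n) / (1 - g)^2   # delta method
  expect_lt(abs(gt$ratio - 0.24), 3 * se_ratio)
  # measured ratio equals the recorded truth exactly
  expect_equal(gt$ratio, sum(truth != "t") / sum(truth == "t"))
})

test_that("aligned all-trans chains give a flat S_CH profile", {
  tb <- generate_chain_conformations(n_chains = 3, gauche_fraction = 0,
                                     align = 3, seed = 4)
  prof <- order_parameter_profile(tb)
  expect_lt(max(abs(diff(prof$S_CH))), 1e-6)
  # geometry oracle: C-H bonds of an all-trans chain lie in the plane
  # perpendicular to the chain axis up to the tetrahedral tilt, so S_CH
  # equals (3 cos^2(90) - 1)/2 = -0.5 when the H-C-H plane is normal to
  # the axis; with the C-C-C bisector tilt the exact value follows from
  # the constructed geometry of the first interior carbon.
  lb <- tb$labels
  h1 <- which(lb$role == "H")[1]
  c1 <- lb$bonded_to[h1]
  v <- tb$positions[1, h1, ] - tb$positions[1, c1, ]
  expected <- 0.5 * (3 * (v[3] / sqrt(sum(v^2)))^2 - 1)
  expect_equal(prof$S_CH[1], expected, tolerance = 1e-9)
})
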