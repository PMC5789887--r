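test_that("ISF is exactly 1 at t = 0 and for static particles", {
  pos <- array(stats::rnorm(2 * 50 * 3), dim = c(2, 50, 3))
  pos[2, , ] <- pos[1, , ]   # frozen
  tb <- trajectory_bundle(pos, dt = 1)
  isf <- compute_isf(tb, q = c(0.7, 1.4), max_lag = 1)
  expect_equal(isf$isf, rep(1, 4), tolerance = 1e-12)
})

test_that("free 3D diffusion matches exp(-D Q^2 t) within 3 SE", {
  tb <- generate_trajectory(n_particles = 1000, n_frames = 240, dt = 0.25,
                            D_lat = 0, R = Inf, D_sphere = 0.1, seed = 2)
  isf <- compute_isf(tb, q = 1.0, max_lag = 40, n_origins = 5)
  th <- exp(-0.1 * 1.0^2 * isf$t_ps)
  i <- isf$t_ps > 0
  expect_lt(max(abs(isf$isf - th)[i] / isf$stderr[i]), 3)
  expect_equal(isf$isf[isf$t_ps == 0], 1, tolerance = 1e-12)
})

test_that("wrapped coordinates are detected and refused", {
  pos <- array(0, dim = c(3, 2, 3))
  pos[2, 1, 1] <- 30   # jump beyond box/2
  tb <- trajectory_bundle(pos, dt = 1, box = c(40, 40, 40))
  expect_error(compute_isf(tb, q = 1, max_lag = 1), "unwrap")
})

test_that("three-process decomposition inverts noiseless curves exactly", {
  t_ps <- seq(0, 400, by = 0.5)
  y <- exp(-0.002 * t_ps) * (0.6 + 0.4 * exp(-0.05 * t_ps)) *
    (0.8 + 0.2 * exp(-1.5 * t_ps))
  f <- fit_isf_three_process(t_ps, y, seed = 4)
  expect_equal(f$A1, 0.6, tolerance = 1e-6)
  expect_equal(f$A2, 0.8, tolerance = 1e-6)
  expect_equal(f$Gamma_lat, 0.002, tolerance = 1e-6)
  expect_equal(f$Gamma_int, 0.05, tolerance = 1e-6)
  expect_equal(f$Gamma_fast, 1.5, tolerance = 1e-6)
  expect_true(f$Gamma_fast > f$Gamma_int && f$Gamma_int > f$Gamma_lat)
})

test_that("a single exponential flags the faster processes unidentifiable", {
  t_ps <- seq(0, 400, by = 1)
  y <- exp(-0.01 * t_ps)
  f <- fit_isf_three_process(t_ps, y, seed = 5)
  expect_equal(f$Gamma_lat, 0.01, tolerance = 1e-4)
  expect_match(paste(f$flags, collapse = ";"), "unidentifiable")
})

test_that("three-process rates are recovered within 5% under 1% noise", {
  # two-resolution time grid: a finely sampled short-time stretch resolves
  # the fast process, a coarser long run the slow ones (the standard
  # dual-run recording protocol)
  t_ps <- c(seq(0, 10, by = 0.02), seq(10.5, 400, by = 0.5))
  base <- exp(-0.002 * t_ps) * (0.6 + 0.4 * exp(-0.05 * t_ps)) *
    (0.8 + 0.2 * exp(-1.5 * t_ps))
  rel <- t(vapply(1:60, function(s) {
    set.seed(s)
    y <- base + stats::rnorm(length(t_ps), 0, 0.01)
    f <- fit_isf_three_process(t_ps, y, n_starts = 4, seed = s)
    abs(c(f$Gamma_lat / 0.002, f$Gamma_int / 0.05, f$Gamma_fast / 1.5) - 1)
  }, numeric(3)))
  expect_lt(stats::median(rel[, 1]), 0.05)
  expect_lt(stats::median(rel[, 2]), 0.05)
  expect_lt(stats::median(rel[, 3]), 0.05)
})

test_that("order parameter hits its exact bounds on aligned fixtures", {
  lab <- data.frame(role = c("C", "H"), chain = 1,
                    carbon_index = c(1, 1), bonded_to = c(NA, 1))
  par <- array(0, c(2, 2, 3)); par[, 2, 3] <- 1.09   # C-H along normal
  expect_equal(order_parameter_profile(trajectory_bundle(par, 1, lab))$S_CH, 1)
  per <- array(0, c(2, 2, 3)); per[, 2, 1] <- 1.09   # perpendicular
  expect_equal(order_parameter_profile(trajectory_bundle(per, 1, lab))$S_CH,
               -0.5)
})

test_that("order parameter vanishes for isotropic orientations", {
  set.seed(3)
  n <- 5e4
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  pos <- array(0, c(2, 2 * n, 3))
  pos[1, seq_len(n) + n, ] <- v
  pos[2, , ] <- pos[1, , ]
  lab <- data.frame(role = c(rep("C", n), rep("H", n)), chain = 1,
                    carbon_index = 1,
                    bonded_to = c(rep(NA_integer_, n), seq_len(n)))
  s <- order_parameter_profile(trajectory_bundle(pos, 1, lab))$S_CH
  expect_lt(abs(s), 0.01)
})

test_that("dihedral classifier counts constructed conformations exactly", {
  # chain with 15 dihedrals: 3 gauche (60 deg), 12 trans (180 deg)
  dih <- c(rep(180, 6), rep(60, 3), rep(180, 6))
  ch <- qensbilayer:::build_alkyl_chain(dih)
  pos <- array(0, c(2, nrow(ch$C), 3))
  pos[1, , ] <- ch$C; pos[2, , ] <- ch$C
  lab <- data.frame(role = "C", chain = 1, carbon_index = seq_len(nrow(ch$C)),
                    bonded_to = NA_integer_)
  gt <- gauche_trans_ratio(trajectory_bundle(pos, 1, lab), frames = 1)
  expect_equal(gt$gauche, 3)
  expect_equal(gt$trans, 12)
  expect_equal(gt$ratio, 0.25)
  # 100 degrees falls in neither bin
  ch2 <- qensbilayer:::build_alkyl_chain(c(100, 180))
  expect_equal(abs(qensbilayer:::dihedral_angle(ch2$C[1, ], ch2$C[2, ],
                                                ch2$C[3, ], ch2$C[4, ])),
               100, tolerance = 1e-6)
  pos2 <- array(0, c(2, nrow(ch2$C), 3)); pos2[1, , ] <- ch2$C
  pos2[2, , ] <- ch2$C
  lab2 <- data.frame(role = "C", chain = 1,
                     carbon_index = seq_len(nrow(ch2$C)),
                     bonded_to = NA_integer_)
  gt2 <- gauche_trans_ratio(trajectory_bundle(pos2, 1, lab2), frames = 1)
  expect_equal(gt2$other, 1)
})

test_that("dihedral classification is invariant under reversal and mirror", {
  dih <- c(60, 180, -60, 180, 120)
  ch <- qensbilayer:::build_alkyl_chain(dih)
  n <- nrow(ch$C)
  count <- function(xyz) {
    pos <- array(0, c(2, n, 3)); pos[1, , ] <- xyz; pos[2, , ] <- xyz
    lab <- data.frame(role = "C", chain = 1, carbon_index = seq_len(n),
                      bonded_to = NA_integer_)
    g <- gauche_trans_ratio(trajectory_bundle(pos, 1, lab), frames = 1)
    c(g$gauche, g$trans, g$other)
  }
  fwd <- count(ch$C)
  rev_ <- count(ch$C[n:1, ])                 # chain reversal
  mir <- count(ch$C %*% diag(c(1, 1, -1)))   # phi -> -phi
  expect_equal(fwd, c(2, 2, 1))
  expect_equal(rev_, fwd)
  expect_equal(mir, fwd)
})

test_that("lateral diffusivity is recovered from in-plane ISF decay", {
  tb <- generate_trajectory(n_particles = 600, n_frames = 300, dt = 0.25,
                            D_lat = 0.32, R = 0, D_sphere = 0, seed = 7)
  qv <- c(0.5, 0.8, 1.1)
  isf <- compute_isf(tb, qv, max_lag = 30, n_origins = 8,
                     orientation = "in_plane")
  rates <- vapply(qv, function(qq) {
    sub <- isf[isf$q == qq, ]
    fit_isf_three_process(sub$t_ps, sub$isf, n_starts = 4,
                          seed = 10)$Gamma_lat
  }, numeric(1))
  d <- lateral_diffusivity_from_isf(qv, rates)
  expect_lt(abs(d$D_lat_A2ps / 0.32 - 1), 0.1)
  # zero-displacement trajectory has D = 0
  pos <- array(1, c(5, 20, 3))
  tb0 <- trajectory_bundle(pos, 1)
  isf0 <- compute_isf(tb0, qv, max_lag = 2)
  expect_equal(isf0$isf, rep(1, nrow(isf0)))
})

test_that("doubling displacements quadruples the fitted diffusivity", {
  tb <- generate_trajectory(n_particles = 400, n_frames = 200, dt = 0.5,
                            D_lat = 0.1, R = 0, D_sphere = 0, seed = 9)
  tb2 <- trajectory_bundle(tb$positions * 2, tb$dt, tb$labels)
  qv <- c(0.4, 0.6, 0.8)
  dfit <- function(t) {
    isf <- compute_isf(t, qv, max_lag = 20, n_origins = 8,
                       orientation = "in_plane")
    rates <- vapply(qv, function(qq) {
      sub <- isf[isf$q == qq, ]
      fit_isf_three_process(sub$t_ps, sub$isf, n_starts = 2,
                            seed = 3)$Gamma_lat
    }, numeric(1))
    lateral_diffusivity_from_isf(qv, rates)$D_lat_A2ps
  }
  expect_equal(dfit(tb2) / dfit(tb), 4, tolerance = 0.15)
})
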