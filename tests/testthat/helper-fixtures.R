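# Shared fixtures and independent oracles for the test suite.

# printed-parameter fixtures ------------------------------------------------

coagel_fixture <- function()
  gel_coagel_params(p_x = 0.15, a = 1.7, tau = 2.53, tau_MG = 6.7)

gel_fixture <- function() {
  # D_r = 6.8e10 1/s -> tau = 2 sin^2(pi/12) / D_r
  tau <- 2 * sin(pi / 12)^2 / (6.8e10 * 1e-12)
  gel_coagel_params(p_x = 0.64, a = 1.8, tau = tau, tau_MG = 5.2)
}

fluid_345K_fixture <- function()
  fluid_params(R_min = 0.3, R_max = 5.4,
               D_min = cm2s_to_A2ps(0.6e-6), D_max = cm2s_to_A2ps(26.1e-6),
               tau_MG = 2.6)

instrument_q <- function() seq(0.5, 1.8, by = 0.1)

small_grid <- function() energy_grid(seq(-0.3, 1.0, by = 0.002))

# independent oracles -------------------------------------------------------

# brute-force sphere eigenvalues: sign scan of the central-difference
# derivative of j_l, refined by interval bisection (no recurrence formulas)
oracle_sphere_eigenvalues <- function(l, n_max, dx = 1e-3, h = 1e-6) {
  jl <- function(x) sqrt(pi / (2 * x)) * besselJ(x, l + 0.5)
  f <- function(x) (jl(x + h) - jl(x - h)) / (2 * h)
  lo <- max(0.05, 0.5 * l)
  xs <- seq(lo, l + (n_max + 4) * pi, by = dx)
  fv <- f(xs)
  sgn <- which(fv[-1] * fv[-length(fv)] < 0)
  roots <- numeric(0)
  for (i in sgn[seq_len(min(n_max, length(sgn)))]) {
    a <- xs[i]; b <- xs[i + 1]
    for (k in 1:60) {
      m <- (a + b) / 2
      if (f(a) * f(m) <= 0) b <- m else a <- m
    }
    roots <- c(roots, (a + b) / 2)
  }
  roots
}

# dense-grid half-maximum of a quasielastic profile by monotone
# interpolation (independent of the uniroot-based mixture_hwhm path)
oracle_hwhm <- function(mix, e_max = NULL, n = 20001) {
  if (is.null(e_max)) {
    # expand until the profile has dropped below half maximum
    half <- mixture_quasielastic(mix, 0) / 2
    e_max <- min(mix$gammas)
    while (mixture_quasielastic(mix, e_max) > half) e_max <- e_max * 2
  }
  e <- seq(0, e_max, length.out = n)
  s <- mixture_quasielastic(mix, e)
  half <- s[1] / 2
  i <- which(s <= half)[1]
  # linear interpolation between the bracketing grid points
  e[i - 1] + (half - s[i - 1]) * (e[i] - e[i - 1]) / (s[i] - s[i - 1])
}
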