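# The QENS inference chain: per-Q two-Lorentzian decomposition of
# resolution-convolved spectra, EISF model fits, model-HWHM fits, Fickian
# lateral-diffusion fit, and Arrhenius analysis.

# run expr with a private RNG stream; the caller's stream is untouched
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# bounded multi-start Levenberg-Marquardt; residual_fn(theta) -> residuals.
# starts: matrix (n_starts x p), first row the heuristic start.
multistart_lm <- function(residual_fn, starts, lower, upper,
                          maxiter = 200) {
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(starts[k, ], lower), upper),
      fn = residual_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  best
}

# parameter standard errors from the LM fit's J'J (residuals already
# sigma-scaled, so no reduced-chi^2 rescale)
lm_stderr <- function(fit) {
  h <- fit$hessian
  se <- rep(NA_real_, length(fit$par))
  cv <- try(solve(h), silent = TRUE)
  if (!inherits(cv, "try-error")) {
    d <- diag(cv)
    se[d > 0] <- sqrt(d[d > 0])
  }
  se
}

#' Per-Q spectral decomposition of a measured spectrum
#'
#' Fits the resolution-convolved two-component law to one spectrum by
#' weighted least squares:
#' gel/fluid — `scale * [A L(G_lat) + (1-A) L(G_lat + dG)] (x) R + bg`;
#' coagel — `scale * [A (delta (x) R) + (1-A) L(G_int) (x) R] + bg`
#' (the elastic line is resolution-shaped).  The internal width enters as
#' `dG = Gamma_int >= 0`, so `Gamma_tot >= Gamma_lat` by construction.
#' Backgrounds are flat + linear slope by default (`background = "none"`
#' forces zero).  Optimization is seeded multi-start Levenberg-Marquardt
#' under box bounds.
#'
#' @param spectrum a [qens_spectrum()].
#' @param kernel a [resolution_kernel()] on the same grid step.
#' @param phase `"coagel"`, `"gel"` or `"fluid"` (gel and fluid share the
#'   same per-Q form).
#' @param background `"linear"` (flat + slope) or `"none"`.
#' @param n_starts number of optimizer starts (first is heuristic).
#' @param seed RNG seed for the start dispersion (private stream).
#' @return List of class `per_q_fit` with fields `q`, `A`, `gamma_lat`,
#'   `gamma_int`, `gamma_tot`, `scale`, `bg0`, `bg1`, standard errors
#'   (`*_se`), `flags` (character), and `deviance`.
#' @export
fit_per_q <- function(spectrum, kernel, phase = c("fluid", "gel", "coagel"),
                      background = c("linear", "none"),
                      n_starts = 8L, seed = 1L) {
  phase <- match.arg(phase)
  background <- match.arg(background)
  grid <- spectrum$energies
  e <- as.numeric(grid)
  y <- spectrum$intensity
  sg <- spectrum$sigma
  sg[sg <= 0] <- max(max(sg), 1e-12) * 1e-3 + 1e-12
  nbg <- if (background == "linear") 2L else 0L
  coagel <- phase == "coagel"

  model_values <- function(th) {
    A <- th[1]
    if (coagel) {
      mix <- two_lorentzian_model(A, 0, th[2], q = spectrum$q)
      m <- th[3] * convolved_mixture(mix, grid, kernel)
      bg <- if (nbg) th[4] + th[5] * e else 0
    } else {
      mix <- two_lorentzian_model(A, th[2], th[3], q = spectrum$q)
      m <- th[4] * convolved_mixture(mix, grid, kernel)
      bg <- if (nbg) th[5] + th[6] * e else 0
    }
    m + bg
  }
  resid_fn <- function(th) (model_values(th) - y) / sg

  de <- attr(grid, "de")
  scale0 <- max(sum(y) * de, 1e-12)
  if (coagel) {
    lower <- c(0, 1e-5, 1e-12, if (nbg) c(-Inf, -Inf))
    upper <- c(1, 2, Inf, if (nbg) c(Inf, Inf))
    heur <- c(0.7, 0.05, scale0, if (nbg) c(0, 0))
  } else {
    lower <- c(0, 1e-5, 1e-5, 1e-12, if (nbg) c(-Inf, -Inf))
    upper <- c(1, 1, 2, Inf, if (nbg) c(Inf, Inf))
    heur <- c(0.5, 0.02, 0.1, scale0, if (nbg) c(0, 0))
  }
  starts <- with_local_seed(seed, {
    s <- matrix(rep(heur, each = n_starts), nrow = n_starts)
    if (n_starts > 1) {
      for (k in 2:n_starts) {
        s[k, 1] <- stats::runif(1, 0.05, 0.95)
        if (coagel) {
          s[k, 2] <- exp(stats::runif(1, log(1e-3), log(0.5)))
        } else {
          s[k, 2] <- exp(stats::runif(1, log(1e-3), log(0.2)))
          s[k, 3] <- exp(stats::runif(1, log(5e-3), log(0.8)))
        }
      }
    }
    s
  })
  fit <- multistart_lm(resid_fn, starts, lower, upper)
  th <- fit$par
  se <- lm_stderr(fit)
  flags <- character(0)
  if (th[1] > 1 - 1e-3) flags <- c(flags, "A_at_upper_bound_gamma_tot_unidentifiable")
  if (th[1] < 1e-3) flags <- c(flags, "A_at_lower_bound")
  if (coagel) {
    out <- list(q = spectrum$q, phase = phase, A = th[1],
                gamma_lat = 0, gamma_int = th[2], gamma_tot = th[2],
                scale = th[3],
                bg0 = if (nbg) th[4] else 0, bg1 = if (nbg) th[5] else 0,
                A_se = se[1], gamma_lat_se = 0, gamma_int_se = se[2],
                scale_se = se[3], flags = flags, deviance = fit$deviance,
                fitted = model_values(th))
  } else {
    out <- list(q = spectrum$q, phase = phase, A = th[1],
                gamma_lat = th[2], gamma_int = th[3],
                gamma_tot = th[2] + th[3], scale = th[4],
                bg0 = if (nbg) th[5] else 0, bg1 = if (nbg) th[6] else 0,
                A_se = se[1], gamma_lat_se = se[2], gamma_int_se = se[3],
                scale_se = se[4], flags = flags, deviance = fit$deviance,
                fitted = model_values(th))
  }
  class(out) <- "per_q_fit"
  out
}

#' Per-Q decomposition of a list of spectra
#'
#' @param spectra list of [qens_spectrum()].
#' @inheritParams fit_per_q
#' @return data.frame with one row per Q (fit fields of [fit_per_q()]).
#' @export
fit_per_q_many <- function(spectra, kernel, phase, background = "linear",
                           n_starts = 8L, seed = 1L) {
  rows <- lapply(seq_along(spectra), function(i) {
    f <- fit_per_q(spectra[[i]], kernel, phase, background,
                   n_starts = n_starts, seed = seed + i)
    data.frame(q = f$q, A = f$A, gamma_lat = f$gamma_lat,
               gamma_int = f$gamma_int, gamma_tot = f$gamma_tot,
               scale = f$scale, bg0 = f$bg0, bg1 = f$bg1,
               A_se = f$A_se, gamma_lat_se = f$gamma_lat_se,
               gamma_int_se = f$gamma_int_se,
               flags = paste(f$flags, collapse = ";"))
  })
  do.call(rbind, rows)
}

#' Fit a geometric model to an EISF curve
#'
#' coagel/gel: [eisf_gel_coagel()] with the mobile fraction `p_x` and
#' rotation radius `a` free; fluid: [eisf_fluid()] with `R_min`, `R_max`
#' free (`R_min` bounded below at 0.05 angstrom, where it acts as a
#' nuisance).  Methyl distance `b`, site count `N_s`/`N_c` and hydrogen
#' fractions are held fixed.
#'
#' @param q momentum transfers (>= 4 points).
#' @param A EISF estimates at `q`.
#' @param sigma optional uncertainties on `A` (weights 1/sigma^2).
#' @param phase `"coagel"`, `"gel"` or `"fluid"`.
#' @param b,N_s,N_c fixed geometry.
#' @param n_starts,seed multi-start control.
#' @return List with the fitted parameters (`p_x`, `a` or `R_min`,
#'   `R_max`), standard errors, `fitted` values and `flags`.
#' @export
fit_eisf <- function(q, A, sigma = NULL, phase = c("coagel", "gel", "fluid"),
                     b = 1.8, N_s = 12L, N_c = 18L,
                     n_starts = 8L, seed = 1L) {
  phase <- match.arg(phase)
  stopifnot(length(q) == length(A))
  if (length(q) < 4) stop("need at least 4 Q points for an EISF fit")
  if (any(A > 1 + 2 * (if (is.null(sigma)) 0.05 else sigma)) ||
      any(A < -2 * (if (is.null(sigma)) 0.05 else max(sigma))))
    warning("EISF values outside [0, 1] beyond 2 sigma")
  w <- if (is.null(sigma) || !all(sigma > 0)) rep(1, length(q)) else 1 / sigma
  flags <- character(0)
  if (phase %in% c("coagel", "gel")) {
    resid_fn <- function(th) {
      p <- gel_coagel_params(p_x = th[1], a = th[2], tau = 1, tau_MG = 1,
                             b = b, N_s = N_s)
      (eisf_gel_coagel(q, p) - A) * w
    }
    lower <- c(0, 0.1); upper <- c(1, 6)
    heur <- c(0.4, 1.7)
    starts <- with_local_seed(seed, {
      s <- matrix(rep(heur, each = n_starts), nrow = n_starts)
      if (n_starts > 1) for (k in 2:n_starts)
        s[k, ] <- c(stats::runif(1, 0.02, 0.98), stats::runif(1, 0.5, 4))
      s
    })
    fit <- multistart_lm(resid_fn, starts, lower, upper)
    se <- lm_stderr(fit)
    if (fit$par[1] < 1e-4) flags <- c(flags, "p_x_at_zero_a_unidentifiable")
    p <- gel_coagel_params(p_x = fit$par[1], a = fit$par[2], tau = 1,
                           tau_MG = 1, b = b, N_s = N_s)
    list(phase = phase, p_x = fit$par[1], a = fit$par[2],
         p_x_se = se[1], a_se = se[2],
         fitted = eisf_gel_coagel(q, p), flags = flags,
         deviance = fit$deviance)
  } else {
    # parameterize (R_min, dR >= 0) so R_max >= R_min by construction
    resid_fn <- function(th) {
      p <- fluid_params(R_min = th[1], R_max = th[1] + th[2], D_min = 1,
                        D_max = 1, tau_MG = 1, b = b, N_c = N_c)
      (eisf_fluid(q, p) - A) * w
    }
    lower <- c(0.05, 0); upper <- c(5, 15)
    heur <- c(0.3, 3)
    starts <- with_local_seed(seed, {
      s <- matrix(rep(heur, each = n_starts), nrow = n_starts)
      if (n_starts > 1) for (k in 2:n_starts)
        s[k, ] <- c(stats::runif(1, 0.05, 2), stats::runif(1, 0.5, 8))
      s
    })
    fit <- multistart_lm(resid_fn, starts, lower, upper)
    se <- lm_stderr(fit)
    R_min <- fit$par[1]; R_max <- fit$par[1] + fit$par[2]
    p <- fluid_params(R_min = R_min, R_max = R_max, D_min = 1, D_max = 1,
                      tau_MG = 1, b = b, N_c = N_c)
    list(phase = phase, R_min = R_min, R_max = R_max,
         R_min_se = se[1], R_max_se = sqrt(sum(se^2, na.rm = TRUE)),
         fitted = eisf_fluid(q, p), flags = flags, deviance = fit$deviance)
  }
}

# fast HWHM of a weight/gamma pair set (same math as mixture_hwhm)
.hwhm_wg <- function(w, g, tol = 1e-9) {
  s <- function(e) sum(w * (g / pi) / (g^2 + e^2))
  s0 <- s(0)
  f <- function(e) s(e) - s0 / 2
  hi <- max(g); while (f(hi) > 0) hi <- hi * 2
  lo <- min(g) / 2; while (f(lo) < 0) lo <- lo / 2
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Fit the internal-motion rates to an observed HWHM curve
#'
#' The model half-width has no closed form, so each objective evaluation
#' computes it numerically from the phase's multi-Lorentzian quasielastic
#' profile.  Geometry from the EISF stage is held fixed; free parameters
#' are the rates: coagel/gel — jump time `tau` (reported as rotational
#' diffusion constant `D_r`) and methyl time `tau_MG`; fluid — `D_min`,
#' `D_max` (parameterized as `D_min + dD`) and `tau_MG`.  The quasielastic
#' structure factors depend only on the fixed geometry, so they are
#' precomputed once per Q.
#'
#' @param q momentum transfers (1/angstrom).
#' @param gamma_int observed internal HWHMs (meV) at `q`.
#' @param sigma optional uncertainties (weights 1/sigma^2).
#' @param phase `"coagel"`, `"gel"` or `"fluid"`.
#' @param geometry for coagel/gel a list with `p_x`, `a` (from
#'   [fit_eisf()]); for fluid a list with `R_min`, `R_max`.
#' @param b,N_s,N_c fixed geometry.
#' @param eig eigenvalue table (fluid).
#' @param n_starts,seed multi-start control.
#' @return List with fitted rates: coagel/gel — `tau` (ps), `D_r_per_s`
#'   (1/s), `tau_MG` (ps); fluid — `D_min`, `D_max` (angstrom^2/ps),
#'   `D_min_cm2s`, `D_max_cm2s`, `tau_MG` (ps); plus `fitted` HWHMs.
#' @export
fit_hwhm_internal <- function(q, gamma_int, sigma = NULL,
                              phase = c("coagel", "gel", "fluid"),
                              geometry, b = 1.8, N_s = 12L, N_c = 18L,
                              eig = sphere_eigenvalues(),
                              n_starts = 8L, seed = 1L) {
  phase <- match.arg(phase)
  stopifnot(length(q) == length(gamma_int))
  w <- if (is.null(sigma) || !all(sigma > 0)) rep(1, length(q)) else 1 / sigma
  hp <- hydrogen_partition()
  if (phase %in% c("coagel", "gel")) {
    stopifnot(!is.null(geometry$p_x), !is.null(geometry$a))
    # per-Q fixed weights: methyl quasielastic + chain jump lines
    pre <- lapply(q, function(qq) {
      elm <- (1 + 2 * sph_bessel_j(0, qq * b)) / 3
      B <- jump_rotation_structure_factors(qq * geometry$a, N_s)
      list(w_mg = hp$P_h * (1 - elm),
           w_chain = geometry$p_x * hp$P_t * B[-1],
           sin2 = sin(seq_len(N_s - 1) * pi / N_s)^2)
    })
    model_fn <- function(th) {  # th = (tau, tau_MG)
      vapply(pre, function(p) {
        g <- c(3 * hbar_meV_ps / th[2],
               hbar_meV_ps * 2 * p$sin2 / th[1])
        .hwhm_wg(c(p$w_mg, p$w_chain), g)
      }, numeric(1))
    }
    resid_fn <- function(th) (model_fn(th) - gamma_int) * w
    lower <- c(0.05, 0.1); upper <- c(500, 500)
    heur <- c(2, 5)
    starts <- with_local_seed(seed, {
      s <- matrix(rep(heur, each = n_starts), nrow = n_starts)
      if (n_starts > 1) for (k in 2:n_starts)
        s[k, ] <- exp(stats::runif(2, log(0.3), log(50)))
      s
    })
    fit <- multistart_lm(resid_fn, starts, lower, upper)
    se <- lm_stderr(fit)
    tau <- fit$par[1]; tau_MG <- fit$par[2]
    list(phase = phase, tau = tau, tau_MG = tau_MG,
         tau_se = se[1], tau_MG_se = se[2],
         D_r_per_ps = (2 / tau) * sin(pi / N_s)^2,
         D_r_per_s = (2 / tau) * sin(pi / N_s)^2 * 1e12,
         fitted = model_fn(fit$par), deviance = fit$deviance)
  } else {
    stopifnot(!is.null(geometry$R_min), !is.null(geometry$R_max))
    i <- seq_len(N_c)
    fi <- if (N_c > 1) (i - 1) / (N_c - 1) else 0
    R_i <- fi * (geometry$R_max - geometry$R_min) + geometry$R_min
    pre <- lapply(q, function(qq) {
      elm <- (1 + 2 * sph_bessel_j(0, qq * b)) / 3
      ws <- list(); rate <- list(); site <- list()
      for (k in i) {
        sf <- sphere_structure_factors(qq * R_i[k], eig)
        ws[[k]] <- hp$P_t / N_c * sf$weights
        rate[[k]] <- sf$x2 / R_i[k]^2   # multiply by D_i for the HWHM
        site[[k]] <- rep(fi[k], length(sf$weights))
      }
      list(w_mg = hp$P_h * (1 - elm), w = unlist(ws),
           base = unlist(rate), f = unlist(site))
    })
    model_fn <- function(th) {  # th = (D_min, dD, tau_MG)
      vapply(pre, function(p) {
        Di <- th[1] + p$f * th[2]
        g <- c(3 * hbar_meV_ps / th[3], hbar_meV_ps * p$base * Di)
        .hwhm_wg(c(p$w_mg, p$w), g)
      }, numeric(1))
    }
    resid_fn <- function(th) (model_fn(th) - gamma_int) * w
    lower <- c(1e-4, 0, 0.1); upper <- c(5, 20, 500)
    heur <- c(0.01, 0.2, 3)
    starts <- with_local_seed(seed, {
      s <- matrix(rep(heur, each = n_starts), nrow = n_starts)
      if (n_starts > 1) for (k in 2:n_starts)
        s[k, ] <- c(exp(stats::runif(1, log(1e-3), log(0.5))),
                    exp(stats::runif(1, log(0.02), log(2))),
                    exp(stats::runif(1, log(0.5), log(20))))
      s
    })
    fit <- multistart_lm(resid_fn, starts, lower, upper)
    se <- lm_stderr(fit)
    D_min <- fit$par[1]; D_max <- fit$par[1] + fit$par[2]
    list(phase = phase, D_min = D_min, D_max = D_max,
         D_min_cm2s = A2ps_to_cm2s(D_min), D_max_cm2s = A2ps_to_cm2s(D_max),
         tau_MG = fit$par[3], tau_MG_se = se[3],
         fitted = model_fn(fit$par), deviance = fit$deviance)
  }
}

#' Fickian fit of the lateral HWHM against Q^2
#'
#' Weighted zero-intercept linear fit `Gamma_lat = hbar D Q^2`; the slope
#' (meV A^2) divided by hbar gives `D` in A^2/ps, reported in cm^2/s.
#'
#' @param q momentum transfers (1/angstrom), >= 3 points.
#' @param gamma_lat lateral HWHMs (meV).
#' @param sigma optional uncertainties on `gamma_lat`.
#' @return List with `D_lat_cm2s`, `D_lat_A2ps`, `slope_meVA2`, `slope_se`,
#'   `D_lat_se_cm2s`.
#' @export
fit_fickian <- function(q, gamma_lat, sigma = NULL) {
  stopifnot(length(q) == length(gamma_lat))
  if (length(q) < 3) stop("need at least 3 (Q, Gamma) points")
  w <- if (is.null(sigma) || !all(sigma > 0)) rep(1, length(q)) else 1 / sigma^2
  x <- q^2
  slope <- sum(w * x * gamma_lat) / sum(w * x^2)
  if (slope < 0) stop("negative Fickian slope: Gamma_lat decreasing with Q^2")
  res <- gamma_lat - slope * x
  dof <- length(q) - 1
  s2 <- sum(w * res^2) / max(dof, 1)
  slope_se <- sqrt(s2 / sum(w * x^2))
  D <- slope / hbar_meV_ps
  list(D_lat_cm2s = A2ps_to_cm2s(D), D_lat_A2ps = D,
       slope_meVA2 = slope, slope_se = slope_se,
       D_lat_se_cm2s = A2ps_to_cm2s(slope_se / hbar_meV_ps))
}

#' Arrhenius fit of diffusion coefficients
#'
#' Least squares of `ln D` against `1/T`; the activation energy is
#' `E_a = -slope * R` (kcal/mol) and the prefactor `D_0 = exp(intercept)`.
#'
#' @param T_K temperatures (K), >= 2 values.
#' @param D_cm2s diffusion coefficients (cm^2/s), all > 0.
#' @return List with `E_a_kcal_mol`, `D_0_cm2s`, `covariance` (2x2 for
#'   intercept/slope; NA for exactly two points).
#' @export
fit_arrhenius <- function(T_K, D_cm2s) {
  stopifnot(length(T_K) == length(D_cm2s))
  if (length(T_K) < 2) stop("need at least 2 (T, D) pairs")
  if (any(D_cm2s <= 0)) stop("all diffusion coefficients must be positive")
  fit <- stats::lm(log(D_cm2s) ~ I(1 / T_K))
  sl <- stats::coef(fit)[2]
  # vcov warns on numerically perfect fits; the covariance is still valid
  cv <- if (length(T_K) > 2) suppressWarnings(stats::vcov(fit))
  else matrix(NA_real_, 2, 2)
  list(E_a_kcal_mol = -as.numeric(sl) * rgas_kcal_molK,
       D_0_cm2s = exp(as.numeric(stats::coef(fit)[1])),
       covariance = cv)
}

#' Full QENS inference chain for one phase/temperature
#'
#' Runs [fit_per_q_many()] on the spectra, then [fit_eisf()] on the
#' recovered A(Q), [fit_hwhm_internal()] on Gamma_int(Q) with the EISF
#' geometry fixed, and (gel/fluid) [fit_fickian()] on Gamma_lat(Q^2) —
#' the sequential per-temperature analysis of backscattering practice.
#'
#' @param spectra list of [qens_spectrum()] at the measured Q values.
#' @param kernel resolution kernel.
#' @param phase phase label.
#' @param n_starts,seed optimizer control, forwarded to each stage.
#' @param background per-Q background model.
#' @return List with `per_q` (data.frame), `eisf`, `hwhm`, `fickian`
#'   (NULL for coagel).
#' @export
qens_inference_chain <- function(spectra, kernel, phase,
                                 n_starts = 8L, seed = 1L,
                                 background = "linear") {
  pq <- fit_per_q_many(spectra, kernel, phase, background,
                       n_starts = n_starts, seed = seed)
  ef <- fit_eisf(pq$q, pq$A, sigma = pq$A_se, phase = phase,
                 n_starts = n_starts, seed = seed + 1000L)
  geometry <- if (phase == "fluid")
    list(R_min = ef$R_min, R_max = ef$R_max)
  else list(p_x = ef$p_x, a = ef$a)
  hw <- fit_hwhm_internal(pq$q, pq$gamma_int, sigma = pq$gamma_int_se,
                          phase = phase, geometry = geometry,
                          n_starts = n_starts, seed = seed + 2000L)
  fk <- if (phase == "coagel") NULL else
    fit_fickian(pq$q, pq$gamma_lat, sigma = pq$gamma_lat_se)
  list(per_q = pq, eisf = ef, hwhm = hw, fickian = fk)
}
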