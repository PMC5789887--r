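# Incoherent scattering laws for the three DODAB bilayer phases.
#
# All models decompose, before instrument-resolution convolution, into an
# elastic delta plus a finite set of zero-centred Lorentzians
# (`lorentzian_mixture`).  Phases:
#   coagel/gel — methyl 3-fold reorientation (head) + uniaxial jump rotation
#                of a mobile fraction p_x of chain hydrogens on a circle of
#                radius a with N_s sites;
#   fluid      — methyl 3-fold reorientation + localized translational
#                diffusion (LTD) of chain hydrogens confined in spheres with
#                linearly distributed radii R_i and diffusivities D_i
#                (Volino–Dianoux reflecting-sphere eigenmodes).

# ---------------------------------------------------------------------------
# parameter records

#' Internal-motion parameters for the coagel and gel phases
#'
#' @param p_x mobile fraction of alkyl-chain hydrogens, in \[0, 1\].
#' @param a radius of gyration of the chain hydrogens about the chain axis
#'   (angstrom).
#' @param tau mean residence time between successive site jumps (ps).
#' @param tau_MG mean residence time of a methyl hydrogen on a site (ps).
#' @param b methyl H-H distance (angstrom), default 1.8.
#' @param N_s number of equivalent jump sites on the circle (>= 2); 12 mimics
#'   continuous uniaxial rotational diffusion over the instrument Q range.
#' @param P_h,P_t head/tail hydrogen fractions; defaults from
#'   [hydrogen_partition()] (6/80 and 74/80 for DODAB).
#' @return List of class `gel_coagel_params`; carries the derived rotational
#'   diffusion constant `D_r = (2/tau) sin^2(pi/N_s)` (1/ps).
#' @export
gel_coagel_params <- function(p_x, a, tau, tau_MG, b = 1.8, N_s = 12L,
                              P_h = NULL, P_t = NULL) {
  hp <- hydrogen_partition()
  if (is.null(P_h)) P_h <- hp$P_h
  if (is.null(P_t)) P_t <- hp$P_t
  stopifnot(p_x >= 0, p_x <= 1, a > 0, b > 0, tau > 0, tau_MG > 0, N_s >= 2)
  if (abs(P_h + P_t - 1) > 1e-9) stop("P_h + P_t must equal 1")
  structure(list(p_x = p_x, a = a, b = b, tau = tau, tau_MG = tau_MG,
                 N_s = as.integer(N_s), P_h = P_h, P_t = P_t,
                 D_r = (2 / tau) * sin(pi / N_s)^2),
            class = "gel_coagel_params")
}

#' Internal-motion parameters for the fluid phase (LTD model)
#'
#' Confinement radii and diffusivities increase linearly along the chain:
#' `R_i = (i-1)/(N_c-1) (R_max - R_min) + R_min` and likewise for `D_i`,
#' with site 1 next to the head group and site `N_c` at the chain end.
#'
#' @param R_min,R_max smallest/largest confinement radii (angstrom),
#'   `0 < R_min <= R_max`.
#' @param D_min,D_max smallest/largest diffusivities (angstrom^2/ps),
#'   `0 < D_min <= D_max`.
#' @param tau_MG methyl residence time (ps).
#' @param N_c number of CH2 sites along the chain (default 18).
#' @inheritParams gel_coagel_params
#' @return List of class `fluid_params` carrying the per-site vectors
#'   `R_i`, `D_i`.
#' @export
fluid_params <- function(R_min, R_max, D_min, D_max, tau_MG, b = 1.8,
                         N_c = 18L, P_h = NULL, P_t = NULL) {
  hp <- hydrogen_partition()
  if (is.null(P_h)) P_h <- hp$P_h
  if (is.null(P_t)) P_t <- hp$P_t
  stopifnot(R_min > 0, R_max >= R_min, D_min > 0, D_max >= D_min,
            tau_MG > 0, b > 0, N_c >= 1)
  if (abs(P_h + P_t - 1) > 1e-9) stop("P_h + P_t must equal 1")
  i <- seq_len(N_c)
  f <- if (N_c > 1) (i - 1) / (N_c - 1) else rep(0, N_c)
  structure(list(R_min = R_min, R_max = R_max, D_min = D_min, D_max = D_max,
                 tau_MG = tau_MG, b = b, N_c = as.integer(N_c),
                 P_h = P_h, P_t = P_t,
                 R_i = f * (R_max - R_min) + R_min,
                 D_i = f * (D_max - D_min) + D_min),
            class = "fluid_params")
}

#' Lateral (whole-lipid) diffusion model
#'
#' Continuous Fickian diffusion in the membrane plane: the lateral
#' quasielastic HWHM is \eqn{\Gamma_{lat}(Q) = \hbar D_{lat} Q^2} with
#' \eqn{\hbar} in meV.ps and `D_lat` in angstrom^2/ps.
#'
#' @param D_lat_cm2s lateral diffusion coefficient (cm^2/s), >= 0.
#' @param E_a,D_0 optional Arrhenius activation energy (kcal/mol) and
#'   prefactor (cm^2/s), for bookkeeping.
#' @return List of class `lateral_model`.
#' @export
lateral_model <- function(D_lat_cm2s, E_a = NA_real_, D_0 = NA_real_) {
  stopifnot(D_lat_cm2s >= 0)
  structure(list(D_lat_cm2s = D_lat_cm2s,
                 D_lat_A2ps = cm2s_to_A2ps(D_lat_cm2s),
                 E_a = E_a, D_0 = D_0),
            class = "lateral_model")
}

#' Lateral Lorentzian HWHM at momentum transfer Q
#' @param q momentum transfer (1/angstrom), vectorized.
#' @param lateral a [lateral_model()].
#' @return HWHM (meV).
#' @export
gamma_lateral <- function(q, lateral) hbar_meV_ps * lateral$D_lat_A2ps * q^2

# ---------------------------------------------------------------------------
# spherical Bessel functions

#' Spherical Bessel function of the first kind
#'
#' @param l non-negative integer order.
#' @param x non-negative numeric vector.
#' @return `j_l(x)`; small arguments use the leading series term
#'   `x^l / (2l+1)!!` to avoid 0/0.
#' @export
sph_bessel_j <- function(l, x) {
  stopifnot(l >= 0, all(x >= 0))
  out <- numeric(length(x))
  small <- x < 1e-6
  if (any(small)) {
    dfact <- prod(seq(1, 2 * l + 1, by = 2))
    out[small] <- x[small]^l / dfact
  }
  if (any(!small)) {
    xs <- x[!small]
    out[!small] <- sqrt(pi / (2 * xs)) * besselJ(xs, l + 0.5)
  }
  out
}

# derivative j_l'(x); for l = 0 this is -j_1(x)
sph_bessel_j_prime <- function(l, x) {
  if (l == 0) return(-sph_bessel_j(1, x))
  sph_bessel_j(l - 1, x) - (l + 1) / x * sph_bessel_j(l, x)
}

# ---------------------------------------------------------------------------
# jump rotation on a circle (coagel/gel alkyl chains)

#' Structure factors for jump rotation among N_s sites on a circle
#'
#' \eqn{B_n(Qa) = (1/N_s) \sum_{i=1}^{N_s} j_0(2Qa \sin(\pi i/N_s))
#' \cos(2\pi n i/N_s)} for `n = 0 .. N_s-1`.  The same summation limits are
#' used for the elastic `B_0` and the quasielastic terms, which preserves
#' the sum rule `sum(B) = 1` exactly.
#'
#' @param q_a dimensionless product Q*a, >= 0.
#' @param n_s number of sites (>= 2).
#' @return Numeric vector `c(B_0, B_1, ..., B_{N_s-1})`.
#' @export
jump_rotation_structure_factors <- function(q_a, n_s) {
  if (n_s < 2) stop("n_s must be at least 2")
  stopifnot(q_a >= 0)
  i <- seq_len(n_s)
  j0i <- sph_bessel_j(0, 2 * q_a * abs(sin(pi * i / n_s)))
  vapply(0:(n_s - 1), function(n) mean(j0i * cos(2 * pi * n * i / n_s)),
         numeric(1))
}

#' Uniaxial jump-rotation scattering law as a spectral mixture
#'
#' Elastic weight `B_0(Qa)` plus `N_s - 1` Lorentzians with HWHMs
#' \eqn{\hbar/\tau_n}, \eqn{\tau_n^{-1} = (2/\tau)\sin^2(n\pi/N_s)}.
#'
#' @param q momentum transfer (1/angstrom).
#' @param params a [gel_coagel_params()]; only `a`, `tau`, `N_s` are used.
#' @return A [lorentzian_mixture()] with total weight 1.
#' @export
uniaxial_rotation_model <- function(q, params) {
  B <- jump_rotation_structure_factors(q * params$a, params$N_s)
  n <- seq_len(params$N_s - 1)
  gam <- hbar_meV_ps * (2 / params$tau) * sin(n * pi / params$N_s)^2
  # sites n and N_s - n share the same rate; weights may be ~0 at Qa = 0
  lorentzian_mixture(elastic = B[1], weights = B[-1], gammas = gam, q = q)
}

#' @describeIn uniaxial_rotation_model Quasielastic spectral density at
#'   energies `e` (meV); the elastic weight is attached as attribute
#'   `"elastic"`.
#' @param e energy transfers (meV).
#' @export
uniaxial_rotation_sqw <- function(q, e, params) {
  mix <- uniaxial_rotation_model(q, params)
  structure(mixture_quasielastic(mix, e), elastic = mix$elastic)
}

# ---------------------------------------------------------------------------
# methyl three-fold reorientation (head group)

#' Methyl three-fold jump reorientation as a spectral mixture
#'
#' Three-site jumps of methyl hydrogens on a circle with H-H distance `b`:
#' elastic fraction \eqn{(1 + 2 j_0(Qb))/3} and a single Lorentzian of HWHM
#' \eqn{3\hbar/\tau_{MG}} carrying the complement.
#'
#' @param q momentum transfer (1/angstrom).
#' @param b methyl H-H distance (angstrom).
#' @param tau_MG methyl residence time (ps).
#' @return A [lorentzian_mixture()] with total weight 1.
#' @export
methyl_3fold_model <- function(q, b, tau_MG) {
  stopifnot(b > 0, tau_MG > 0)
  el <- (1 + 2 * sph_bessel_j(0, q * b)) / 3
  lorentzian_mixture(elastic = el, weights = 1 - el,
                     gammas = 3 * hbar_meV_ps / tau_MG, q = q)
}

#' @describeIn methyl_3fold_model Quasielastic density with `"elastic"`
#'   attribute.
#' @param e energy transfers (meV).
#' @export
methyl_3fold_sqw <- function(q, e, b, tau_MG) {
  mix <- methyl_3fold_model(q, b, tau_MG)
  structure(mixture_quasielastic(mix, e), elastic = mix$elastic)
}

# ---------------------------------------------------------------------------
# diffusion in a reflecting sphere (Volino–Dianoux)

.qb_cache <- new.env(parent = emptyenv())

#' Eigenvalue roots for diffusion inside a reflecting sphere
#'
#' The reflecting boundary condition quantizes the radial modes at the
#' stationary points of the spherical Bessel functions: `x_n^l` is the n-th
#' positive root of \eqn{d j_l(x)/dx = 0} (for `l = 0` these are the roots
#' of \eqn{j_1(x) = 0}).  Roots are located by a fine sign-change scan and
#' polished with `uniroot`; results are memoized.
#'
#' @param l_max,n_max truncation orders (>= 1).
#' @return List of class `sphere_eigenvalues` with matrix `x` of dimension
#'   `(l_max + 1) x n_max` (rows l = 0..l_max) and `l_max`, `n_max`.
#' @export
sphere_eigenvalues <- function(l_max = 20L, n_max = 20L) {
  stopifnot(l_max >= 1, n_max >= 1)
  key <- sprintf("eig_%d_%d", l_max, n_max)
  if (!is.null(.qb_cache[[key]])) return(.qb_cache[[key]])
  x <- matrix(NA_real_, nrow = l_max + 1, ncol = n_max)
  for (l in 0:l_max) {
    f <- function(z) sph_bessel_j_prime(l, z)
    roots <- numeric(0)
    lo <- max(0.05, 0.5 * l)   # j_l' > 0 until the first maximum past ~l
    step <- 0.02
    z <- lo
    fz <- f(z)
    while (length(roots) < n_max) {
      z2 <- z + step
      fz2 <- f(z2)
      if (is.finite(fz) && is.finite(fz2) && fz * fz2 < 0) {
        r <- stats::uniroot(f, c(z, z2), tol = 1e-12)$root
        roots <- c(roots, r)
      }
      z <- z2; fz <- fz2
      if (z > l + (n_max + 5) * pi + 20)
        stop(sprintf("eigenvalue search failed to converge at l=%d, n=%d",
                     l, length(roots) + 1))
    }
    x[l + 1, ] <- roots[seq_len(n_max)]
  }
  out <- structure(list(x = x, l_max = l_max, n_max = n_max),
                   class = "sphere_eigenvalues")
  .qb_cache[[key]] <- out
  out
}

#' Structure factors of diffusion in a reflecting sphere
#'
#' Elastic term \eqn{A_0^0(QR) = [3 j_1(QR)/(QR)]^2}; quasielastic terms
#' \eqn{A_n^l(QR) = \frac{6 (x_n^l)^2}{(x_n^l)^2 - l(l+1)}
#' \left[\frac{QR\,j_{l+1}(QR) - l\,j_l(QR)}{(QR)^2 - (x_n^l)^2}\right]^2},
#' with the removable singularity at `QR = x_n^l` evaluated analytically.
#' Completeness: \eqn{A_0^0 + \sum_{l,n} (2l+1) A_n^l = 1}.
#'
#' @param qr dimensionless product Q*R, >= 0.
#' @param eig a [sphere_eigenvalues()] table.
#' @param weight_cutoff terms with `(2l+1) A_n^l` below this are dropped
#'   (speed; set 0 to keep all).
#' @return List with `elastic` (A_0^0), and vectors `weights`
#'   (`(2l+1) A_n^l`), `x2` (`(x_n^l)^2`) for the retained terms, plus
#'   `closure` = elastic + sum(weights before cutoff).
#' @export
sphere_structure_factors <- function(qr, eig = sphere_eigenvalues(),
                                     weight_cutoff = 1e-8) {
  stopifnot(qr >= 0)
  if (qr == 0)
    return(list(elastic = 1, weights = numeric(0), x2 = numeric(0),
                closure = 1))
  a00 <- (3 * sph_bessel_j(1, qr) / qr)^2
  wlist <- x2list <- vector("list", eig$l_max + 1)
  for (l in 0:eig$l_max) {
    xs <- eig$x[l + 1, ]
    jl  <- sph_bessel_j(l, qr)
    jl1 <- sph_bessel_j(l + 1, qr)
    num <- qr * jl1 - l * jl
    denom <- qr^2 - xs^2
    pref <- 6 * xs^2 / (xs^2 - l * (l + 1))
    A <- pref * (num / denom)^2
    near <- abs(denom) < 1e-6 * xs^2
    if (any(near)) {
      jlx <- sph_bessel_j(l, xs[near])
      A[near] <- 1.5 * jlx^2 * (xs[near]^2 - l * (l + 1)) / xs[near]^2
    }
    wlist[[l + 1]] <- (2 * l + 1) * A
    x2list[[l + 1]] <- xs^2
  }
  w <- unlist(wlist); x2 <- unlist(x2list)
  closure <- a00 + sum(w)
  keep <- w >= weight_cutoff
  list(elastic = a00, weights = w[keep], x2 = x2[keep], closure = closure)
}

#' Scattering law for diffusion confined to a sphere, as a spectral mixture
#'
#' Lorentzian HWHMs are \eqn{\hbar (x_n^l)^2 D / R^2} (meV); the lowest mode
#' `(x_1^1)^2 = 4.333` sets the Q->0 plateau of the quasielastic half-width.
#'
#' @param q momentum transfer (1/angstrom).
#' @param R sphere radius (angstrom), > 0 (R = 0 degenerates to a pure
#'   elastic line).
#' @param D diffusivity inside the sphere (angstrom^2/ps), > 0.
#' @param eig eigenvalue table.
#' @param closure_tol warn if the truncated structure-factor sum falls below
#'   `1 - closure_tol`.
#' @return A [lorentzian_mixture()].
#' @export
confined_sphere_model <- function(q, R, D, eig = sphere_eigenvalues(),
                                  closure_tol = 1e-3) {
  stopifnot(D > 0, R >= 0)
  if (R == 0) return(lorentzian_mixture(elastic = 1, q = q))
  sf <- sphere_structure_factors(q * R, eig)
  if (sf$closure < 1 - closure_tol)
    warning(sprintf(
      "sphere structure-factor closure %.5f < %.5f at QR = %.3f; increase l_max/n_max",
      sf$closure, 1 - closure_tol, q * R))
  lorentzian_mixture(elastic = sf$elastic, weights = sf$weights,
                     gammas = hbar_meV_ps * sf$x2 * D / R^2, q = q)
}

#' @describeIn confined_sphere_model Quasielastic density with `"elastic"`
#'   attribute.
#' @param e energy transfers (meV).
#' @export
confined_sphere_sqw <- function(q, e, R, D, eig = sphere_eigenvalues()) {
  mix <- confined_sphere_model(q, R, D, eig)
  structure(mixture_quasielastic(mix, e), elastic = mix$elastic)
}

# ---------------------------------------------------------------------------
# EISFs

#' Elastic incoherent structure factor for the coagel and gel phases
#'
#' \deqn{A(Q) = \frac{P_h}{3}(1 + 2 j_0(Qb)) + P_t (1 - p_x) +
#'  P_t \frac{p_x}{N_s} \sum_{i=1}^{N_s} j_0\!\left(2Qa\sin\frac{\pi i}{N_s}\right)}
#'
#' @param q momentum transfer (1/angstrom), vectorized.
#' @param params a [gel_coagel_params()].
#' @return EISF values in \[0, 1\].
#' @export
eisf_gel_coagel <- function(q, params) {
  vapply(q, function(qq) {
    B0 <- jump_rotation_structure_factors(qq * params$a, params$N_s)[1]
    params$P_h / 3 * (1 + 2 * sph_bessel_j(0, qq * params$b)) +
      params$P_t * (1 - params$p_x) + params$P_t * params$p_x * B0
  }, numeric(1))
}

#' Elastic incoherent structure factor for the fluid phase
#'
#' \deqn{A(Q) = \frac{P_h}{3}(1 + 2 j_0(Qb)) +
#'   \frac{P_t}{N_c}\sum_{i=1}^{N_c}\left[\frac{3 j_1(QR_i)}{QR_i}\right]^2}
#'
#' @param q momentum transfer (1/angstrom), vectorized.
#' @param params a [fluid_params()].
#' @return EISF values in \[0, 1\].
#' @export
eisf_fluid <- function(q, params) {
  vapply(q, function(qq) {
    a00 <- vapply(params$R_i, function(R) {
      if (qq * R == 0) 1 else (3 * sph_bessel_j(1, qq * R) / (qq * R))^2
    }, numeric(1))
    params$P_h / 3 * (1 + 2 * sph_bessel_j(0, qq * params$b)) +
      params$P_t * mean(a00)
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# composite internal scattering laws

#' Composite internal-motion scattering law for a given phase
#'
#' Weighted combination of the methyl head-group term and the
#' phase-appropriate alkyl-chain term (jump rotation for coagel/gel,
#' distributed confined spheres for fluid), with hydrogen fractions
#' `P_h`, `P_t` and, for coagel/gel, the mobile fraction `p_x`.  The elastic
#' weight equals the corresponding EISF and the total weight is 1.
#'
#' @param q momentum transfer (1/angstrom).
#' @param phase one of `"coagel"`, `"gel"`, `"fluid"`.
#' @param params a [gel_coagel_params()] (coagel/gel) or [fluid_params()]
#'   (fluid).
#' @param eig eigenvalue table (fluid only).
#' @return A [lorentzian_mixture()].
#' @export
internal_model <- function(q, phase = c("coagel", "gel", "fluid"), params,
                           eig = sphere_eigenvalues()) {
  phase <- match.arg(phase)
  if (phase %in% c("coagel", "gel")) {
    if (!inherits(params, "gel_coagel_params"))
      stop("coagel/gel phases require gel_coagel_params")
    mg <- methyl_3fold_model(q, params$b, params$tau_MG)
    un <- uniaxial_rotation_model(q, params)
    lorentzian_mixture(
      elastic = eisf_gel_coagel(q, params),
      weights = c(params$P_h * mg$weights, params$p_x * params$P_t * un$weights),
      gammas  = c(mg$gammas, un$gammas), q = q)
  } else {
    if (!inherits(params, "fluid_params"))
      stop("fluid phase requires fluid_params")
    mg <- methyl_3fold_model(q, params$b, params$tau_MG)
    w <- list(params$P_h * mg$weights)
    g <- list(mg$gammas)
    for (i in seq_len(params$N_c)) {
      sp <- confined_sphere_model(q, params$R_i[i], params$D_i[i], eig)
      w[[i + 1]] <- params$P_t / params$N_c * sp$weights
      g[[i + 1]] <- sp$gammas
    }
    lorentzian_mixture(elastic = eisf_fluid(q, params),
                       weights = unlist(w), gammas = unlist(g), q = q)
  }
}

#' @describeIn internal_model Quasielastic density at energies `e` with the
#'   elastic weight as attribute `"elastic"`.
#' @param e energy transfers (meV).
#' @export
composite_internal_sqw <- function(q, e, phase, params,
                                   eig = sphere_eigenvalues()) {
  mix <- internal_model(q, phase, params, eig)
  structure(mixture_quasielastic(mix, e), elastic = mix$elastic)
}

#' Numerical half-width of the internal quasielastic component
#'
#' The composite internal laws are multi-Lorentzian, so no analytic HWHM
#' exists; the half-maximum point of the elastic-removed profile is found
#' numerically (see [mixture_hwhm()]).  For confined motion the curve
#' flattens to a finite nonzero value as Q -> 0.
#'
#' @param q momentum transfer (1/angstrom), vectorized.
#' @inheritParams internal_model
#' @return HWHM Gamma_int (meV) at each `q`.
#' @export
model_hwhm <- function(q, phase, params, eig = sphere_eigenvalues()) {
  vapply(q, function(qq) mixture_hwhm(internal_model(qq, phase, params, eig)),
         numeric(1))
}

#' Bilayer scattering law (lateral x internal) as a spectral mixture
#'
#' The working bilayer law: lateral Fickian diffusion convolved with the
#' internal motion.  Because a convolution of Lorentzians is a Lorentzian
#' with summed HWHMs, the default `form = "two_lorentzian"` is
#' `A(Q) L(Gamma_lat) + (1 - A(Q)) L(Gamma_lat + Gamma_int)` with `A(Q)`
#' the phase EISF and `Gamma_int(Q)` the numerically computed half-width
#' of the internal quasielastic profile — the form the per-Q decomposition
#' fits and the physical parameters map onto.  `form = "full"` instead
#' broadens every individual internal Lorentzian by `Gamma_lat`,
#' retaining the complete multi-Lorentzian width distribution (the
#' two-Lorentzian law is its single-width approximation).  The coagel
#' phase has no resolvable lateral motion and keeps its elastic line.
#'
#' @param q momentum transfer (1/angstrom).
#' @param lateral a [lateral_model()], ignored for `phase = "coagel"`.
#' @param form `"two_lorentzian"` (phenomenological bilayer law) or
#'   `"full"` (every internal component broadened individually).
#' @inheritParams internal_model
#' @return A [lorentzian_mixture()].
#' @export
bilayer_model <- function(q, lateral, params,
                          phase = c("gel", "fluid", "coagel"),
                          form = c("two_lorentzian", "full"),
                          eig = sphere_eigenvalues()) {
  phase <- match.arg(phase)
  form <- match.arg(form)
  if (form == "full") {
    mix <- internal_model(q, phase, params, eig)
    if (phase == "coagel") return(mix)
    return(mixture_broaden(mix, gamma_lateral(q, lateral)))
  }
  A <- if (phase == "fluid") eisf_fluid(q, params) else
    eisf_gel_coagel(q, params)
  g_int <- mixture_hwhm(internal_model(q, phase, params, eig))
  g_lat <- if (phase == "coagel") 0 else gamma_lateral(q, lateral)
  two_lorentzian_model(A, g_lat, g_int, q = q)
}

#' @describeIn bilayer_model Quasielastic density with `"elastic"` attribute
#'   (zero elastic weight whenever lateral diffusion is active).
#' @param e energy transfers (meV).
#' @export
bilayer_sqw <- function(q, e, lateral, params, phase = c("gel", "fluid", "coagel"),
                        form = c("two_lorentzian", "full"),
                        eig = sphere_eigenvalues()) {
  mix <- bilayer_model(q, lateral, params, phase, form, eig)
  structure(mixture_quasielastic(mix, e), elastic = mix$elastic)
}

#' Phenomenological two-Lorentzian bilayer law
#'
#' The per-Q fitting form: `A L(Gamma_lat, E) + (1 - A) L(Gamma_tot, E)` with
#' `Gamma_tot = Gamma_lat + Gamma_int` — the exact reduction of the
#' lateral (x) internal convolution when the internal quasielastic part is
#' approximated by a single Lorentzian.
#'
#' @param a EISF weight in \[0, 1\].
#' @param gamma_lat,gamma_int lateral and internal HWHMs (meV), >= 0.
#' @param q bookkeeping momentum transfer.
#' @return A [lorentzian_mixture()]; `gamma_lat = 0` yields an elastic line
#'   plus one Lorentzian.
#' @export
two_lorentzian_model <- function(a, gamma_lat, gamma_int, q = NA_real_) {
  stopifnot(a >= 0, a <= 1, gamma_lat >= 0, gamma_int >= 0)
  if (gamma_lat == 0)
    return(lorentzian_mixture(elastic = a, weights = 1 - a,
                              gammas = max(gamma_int, .Machine$double.eps),
                              q = q))
  lorentzian_mixture(elastic = 0, weights = c(a, 1 - a),
                     gammas = c(gamma_lat, gamma_lat + gamma_int), q = q)
}
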