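# Seeded generators producing inputs with the exact statistical structure
# the analysis assumes: backscattering spectra built from the package's own
# scattering laws with counting noise, Debye-Waller elastic scans, and toy
# trajectories combining 2D lateral Brownian motion, reflecting-sphere
# confined diffusion and a fast two-site jump.  All generators draw from a
# private RNG stream keyed by `seed` (byte-identical outputs per seed) and
# leave the caller's RNG state untouched.

#' Generate a synthetic QENS dataset from a phase model
#'
#' Builds the full bilayer scattering law at each Q (internal model, plus
#' lateral broadening for gel/fluid), convolves it with the resolution
#' kernel, scales the curve to `peak_counts` at its maximum, and applies
#' counting noise.  The generating parameters are returned as a truth
#' record for recovery tests.
#'
#' @param phase `"coagel"`, `"gel"` or `"fluid"`.
#' @param params a [gel_coagel_params()] or [fluid_params()].
#' @param lateral a [lateral_model()] (ignored for coagel).
#' @param q momentum transfers (1/angstrom); instrument range 0.5--1.8.
#' @param grid an [energy_grid()]; default IRIS window.
#' @param resolution a [resolution_kernel()] or a Gaussian FWHM in meV
#'   (default 0.017 = 17 ueV).
#' @param peak_counts counts at the spectrum maximum, > 0.
#' @param noise `"none"`, `"poisson"` or `"gaussian"`.
#' @param gaussian_frac fractional sigma for `noise = "gaussian"`.
#' @param law generative scattering law: `"two_lorentzian"` (the bilayer
#'   law the inference chain fits, with physically derived `A(Q)`,
#'   `Gamma_int(Q)`; exactly invertible up to noise) or `"full"` (complete
#'   multi-Lorentzian width distribution; exposes the single-width
#'   approximation gap of the phenomenological decomposition).
#' @param seed RNG seed.
#' @return List with `spectra` (list of [qens_spectrum()]), `resolution`
#'   (the kernel) and `truth` (generating parameters).
#' @export
generate_qens_dataset <- function(phase, params, lateral = NULL,
                                  q = seq(0.5, 1.8, length.out = 8),
                                  grid = default_energy_grid(),
                                  resolution = 0.017,
                                  peak_counts = 1e4,
                                  noise = c("poisson", "none", "gaussian"),
                                  gaussian_frac = 0.02,
                                  law = c("two_lorentzian", "full"),
                                  seed = 1L) {
  noise <- match.arg(noise)
  law <- match.arg(law)
  stopifnot(peak_counts > 0)
  kernel <- if (inherits(resolution, "resolution_kernel")) resolution
  else gaussian_resolution_kernel(grid, resolution)
  if (phase != "coagel" && is.null(lateral))
    stop("gel/fluid generation requires a lateral_model")
  spectra <- with_local_seed(seed, {
    lapply(q, function(qq) {
      mix <- if (phase == "coagel" && law == "full")
        internal_model(qq, phase, params)
      else bilayer_model(qq, lateral, params, phase, form = law)
      y <- convolved_mixture(mix, grid, kernel)
      s <- peak_counts / max(y)
      counts <- y * s
      if (noise == "poisson") {
        obs <- stats::rpois(length(counts), counts)
        sg <- sqrt(pmax(obs, 1))
      } else if (noise == "gaussian") {
        sg <- gaussian_frac * pmax(counts, max(counts) * 1e-3)
        obs <- counts + stats::rnorm(length(counts), 0, sg)
      } else {
        obs <- counts
        sg <- sqrt(pmax(counts, 1))
      }
      qens_spectrum(qq, grid, obs, sg)
    })
  })
  truth <- list(phase = phase, params = params, lateral = lateral,
                peak_counts = peak_counts, noise = noise, law = law,
                seed = seed)
  list(spectra = spectra, resolution = kernel, truth = truth)
}

#' Generate a fixed-elastic-window scan from an MSD schedule
#'
#' Inverts the Gaussian approximation: `I_el(Q, T) = exp(-u2(T) Q^2 / 6)`
#' relative to the base temperature, optionally multiplied by step factors
#' at configured transition temperatures (sharp intensity losses at a
#' phase change) and by multiplicative Gaussian noise.
#'
#' @param schedule data.frame with columns `T_K` and `u2` (angstrom^2,
#'   >= 0); need not include the base temperature.
#' @param q momentum transfers (1/angstrom).
#' @param cycle `"heating"` or `"cooling"` label for the rows.
#' @param steps optional data.frame with `T_K`, `factor`: intensity is
#'   multiplied by `factor` for all temperatures >= `T_K` (heating) —
#'   an abrupt elastic-intensity drop at a dynamical transition.
#' @param noise_frac fractional Gaussian noise on intensities (0 = none).
#' @param T_min base temperature (K), intensity 1 by construction.
#' @param seed RNG seed.
#' @return An [elastic_scan()] including the base-temperature rows.
#' @export
generate_elastic_scan <- function(schedule, q, cycle = "heating",
                                  steps = NULL, noise_frac = 0,
                                  T_min = 10, seed = 1L) {
  stopifnot(all(schedule$u2 >= 0), all(schedule$T_K > T_min))
  rows <- with_local_seed(seed, {
    g <- expand.grid(T_K = schedule$T_K, Q_invA = q)
    g$u2 <- schedule$u2[match(g$T_K, schedule$T_K)]
    g$I_el <- exp(-g$u2 * g$Q_invA^2 / 6)
    if (!is.null(steps))
      for (k in seq_len(nrow(steps)))
        g$I_el <- g$I_el * ifelse(g$T_K >= steps$T_K[k], steps$factor[k], 1)
    g$sigma <- noise_frac * g$I_el
    if (noise_frac > 0)
      g$I_el <- g$I_el * (1 + stats::rnorm(nrow(g), 0, noise_frac))
    g
  })
  base <- data.frame(T_K = T_min, Q_invA = q, u2 = 0, I_el = 1, sigma = 0)
  out <- rbind(base, rows[, names(base)])
  out$cycle <- cycle
  elastic_scan(out[out$I_el > 0, ], T_min = T_min)
}

#' Generate a toy trajectory with lateral, confined and fast-jump motion
#'
#' Per particle, the position is the sum of three independent processes:
#' a 2D Brownian centre of mass in the membrane plane (per-axis step
#' variance `2 D_lat dt`), a 3D Brownian offset confined to a sphere of
#' radius `R` by radial folding of each step (specular reflection in the
#' small-step limit, preserving the uniform equilibrium density), and an
#' optional two-site telegraph jump of length `jump_dist` with switching
#' rate `jump_rate` along a fixed random axis.
#'
#' @param n_particles number of particles.
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing (ps).
#' @param D_lat lateral diffusivity (angstrom^2/ps), >= 0.
#' @param R confinement radius (angstrom); 0 disables the confined process.
#' @param D_sphere diffusivity inside the sphere (angstrom^2/ps).
#' @param jump_dist site separation of the fast jump (angstrom); 0 disables.
#' @param jump_rate telegraph switching rate (1/ps).
#' @param seed RNG seed.
#' @return A [trajectory_bundle()]; attribute `"truth"` carries the
#'   generating parameters.
#' @export
generate_trajectory <- function(n_particles = 100L, n_frames = 200L,
                                dt = 1, D_lat = 0.05, R = 0,
                                D_sphere = 0.1, jump_dist = 0,
                                jump_rate = 1, seed = 1L) {
  stopifnot(n_frames >= 2, dt > 0, D_lat >= 0, R >= 0, D_sphere >= 0,
            jump_dist >= 0, jump_rate >= 0)
  pos <- with_local_seed(seed, {
    p <- array(0, dim = c(n_frames, n_particles, 3))
    com <- matrix(0, n_particles, 2)
    off <- matrix(0, n_particles, 3)
    jump_axis <- matrix(stats::rnorm(3 * n_particles), n_particles, 3)
    jump_axis <- jump_axis / sqrt(rowSums(jump_axis^2))
    state <- stats::rbinom(n_particles, 1, 0.5)
    sd_lat <- sqrt(2 * D_lat * dt)
    sd_sph <- sqrt(2 * D_sphere * dt)
    p_flip <- min(0.5, jump_rate * dt)
    fill <- function(f) {
      j <- if (jump_dist > 0) (state - 0.5) * jump_dist * jump_axis else 0
      p[f, , 1] <<- com[, 1] + off[, 1] + (if (jump_dist > 0) j[, 1] else 0)
      p[f, , 2] <<- com[, 2] + off[, 2] + (if (jump_dist > 0) j[, 2] else 0)
      p[f, , 3] <<- off[, 3] + (if (jump_dist > 0) j[, 3] else 0)
    }
    fill(1L)
    for (f in 2:n_frames) {
      if (D_lat > 0)
        com <- com + matrix(stats::rnorm(2 * n_particles, 0, sd_lat),
                            n_particles, 2)
      if (R > 0 && D_sphere > 0) {
        off <- off + matrix(stats::rnorm(3 * n_particles, 0, sd_sph),
                            n_particles, 3)
        repeat {
          nr <- sqrt(rowSums(off^2))
          out <- nr > R
          if (!any(out)) break
          off[out, ] <- off[out, , drop = FALSE] *
            ((2 * R - nr[out]) / nr[out])
        }
      }
      if (jump_dist > 0 && p_flip > 0) {
        flip <- stats::runif(n_particles) < p_flip
        state[flip] <- 1L - state[flip]
      }
      fill(f)
    }
    p
  })
  labels <- data.frame(role = "H", chain = seq_len(n_particles),
                       carbon_index = NA_integer_, bonded_to = NA_integer_)
  tb <- trajectory_bundle(pos, dt, labels)
  attr(tb, "truth") <- list(D_lat = D_lat, R = R, D_sphere = D_sphere,
                            jump_dist = jump_dist, jump_rate = jump_rate,
                            seed = seed)
  tb
}

# NeRF atom placement: position D such that |CD| = bond, angle BCD = theta,
# dihedral ABCD = phi (degrees)
place_atom <- function(A, B, C, bond, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  b1 <- B - A; b2 <- C - B
  b2n <- b2 / sqrt(sum(b2^2))
  n <- cross3(b1, b2); n <- n / sqrt(sum(n^2))
  m <- cross3(n, b2n)
  C + bond * (-b2n * cos(th) + m * sin(th) * cos(ph) + n * sin(th) * sin(ph))
}

# ideal-geometry alkyl chain: backbone carbons from a dihedral sequence,
# plus two methylene hydrogens per interior carbon
build_alkyl_chain <- function(dihedrals_deg, bond_cc = 1.54,
                              angle_ccc = 111, bond_ch = 1.09,
                              angle_hch = 107) {
  n_c <- length(dihedrals_deg) + 3L
  C <- matrix(NA_real_, n_c, 3)
  C[1, ] <- c(0, 0, 0)
  C[2, ] <- c(bond_cc, 0, 0)
  a <- (180 - angle_ccc) * pi / 180
  C[3, ] <- C[2, ] + bond_cc * c(cos(a), sin(a), 0)
  for (k in seq_along(dihedrals_deg))
    C[k + 3L, ] <- place_atom(C[k, ], C[k + 1, ], C[k + 2, ], bond_cc,
                              angle_ccc, dihedrals_deg[k])
  # methylene hydrogens on interior carbons
  Hpos <- list(); Hbond <- integer(0)
  alpha <- angle_hch / 2 * pi / 180
  for (i in 2:(n_c - 1)) {
    b1 <- C[i - 1, ] - C[i, ]; b1 <- b1 / sqrt(sum(b1^2))
    b2 <- C[i + 1, ] - C[i, ]; b2 <- b2 / sqrt(sum(b2^2))
    bis <- b1 + b2; bis <- bis / sqrt(sum(bis^2))
    perp <- cross3(b1, b2); perp <- perp / sqrt(sum(perp^2))
    for (sgn in c(1, -1)) {
      Hpos[[length(Hpos) + 1L]] <-
        C[i, ] + bond_ch * (-bis * cos(alpha) + sgn * perp * sin(alpha))
      Hbond <- c(Hbond, i)
    }
  }
  list(C = C, H = do.call(rbind, Hpos), H_bond = Hbond)
}

#' Generate ideal-geometry alkyl chains with known dihedral states
#'
#' Backbone dihedrals are drawn independently: trans (180 deg) with
#' probability `1 - gauche_fraction`, and +60 or -60 deg with probability
#' `gauche_fraction/2` each.  Chains are built with ideal bond lengths and
#' angles (C-C 1.54 A, C-C-C 111 deg, C-H 1.09 A) and two methylene
#' hydrogens per interior carbon; the drawn per-bond states are recorded
#' as ground truth.
#'
#' @param n_chains number of chains.
#' @param n_carbons backbone length (default 18, the DODAB tail).
#' @param gauche_fraction probability of a gauche dihedral, in \[0, 1\].
#' @param align axis (1-3) to rotate each chain's end-to-end vector onto,
#'   or `NULL` to keep build coordinates.
#' @param seed RNG seed.
#' @return A single-frame [trajectory_bundle()]; attribute `"truth"` holds
#'   the per-chain dihedral state matrix (`"t"`, `"g+"`, `"g-"`).
#' @export
generate_chain_conformations <- function(n_chains = 10L, n_carbons = 18L,
                                         gauche_fraction = 0, align = NULL,
                                         seed = 1L) {
  stopifnot(gauche_fraction >= 0, gauche_fraction <= 1, n_carbons >= 4)
  n_dih <- n_carbons - 3L
  built <- with_local_seed(seed, {
    lapply(seq_len(n_chains), function(ic) {
      u <- stats::runif(n_dih)
      st <- ifelse(u < gauche_fraction / 2, "g+",
                   ifelse(u < gauche_fraction, "g-", "t"))
      dih <- ifelse(st == "g+", 60, ifelse(st == "g-", -60, 180))
      ch <- build_alkyl_chain(dih)
      list(state = st, chain = ch)
    })
  })
  pos_list <- list(); lab <- list()
  for (ic in seq_len(n_chains)) {
    ch <- built[[ic]]$chain
    xyz <- rbind(ch$C, ch$H)
    if (!is.null(align)) {
      v <- ch$C[nrow(ch$C), ] - ch$C[1, ]
      xyz <- rotate_onto_axis(xyz, v, align)
    }
    n_c <- nrow(ch$C)
    lab[[ic]] <- data.frame(
      role = c(rep("C", n_c), rep("H", nrow(ch$H))),
      chain = ic,
      carbon_index = c(seq_len(n_c), ch$H_bond),
      bonded_to = c(rep(NA_integer_, n_c), ch$H_bond))
    pos_list[[ic]] <- xyz
  }
  # offset bonded_to into global atom indices
  offset <- 0L
  for (ic in seq_len(n_chains)) {
    nn <- nrow(pos_list[[ic]])
    lab[[ic]]$bonded_to <- lab[[ic]]$bonded_to + offset
    offset <- offset + nn
  }
  pos <- do.call(rbind, pos_list)
  arr <- array(0, dim = c(2, nrow(pos), 3))  # two identical frames
  arr[1, , ] <- pos
  arr[2, , ] <- pos
  tb <- trajectory_bundle(arr, dt = 1, labels = do.call(rbind, lab))
  attr(tb, "truth") <- list(
    states = do.call(rbind, lapply(built, `[[`, "state")),
    gauche_fraction = gauche_fraction, seed = seed)
  tb
}

# rotate coordinates so that vector v maps onto the given axis (1-3)
rotate_onto_axis <- function(xyz, v, axis) {
  v <- v / sqrt(sum(v^2))
  e <- c(0, 0, 0); e[axis] <- 1
  c_ <- sum(v * e)
  if (abs(c_ - 1) < 1e-12) return(xyz)
  if (abs(c_ + 1) < 1e-12) {
    # antiparallel: rotate by pi about any axis perpendicular to e
    p <- if (abs(e[1]) < 0.9) cross3(e, c(1, 0, 0)) else cross3(e, c(0, 1, 0))
    p <- p / sqrt(sum(p^2))
    Rm <- 2 * outer(p, p) - diag(3)
    return(xyz %*% t(Rm))
  }
  k <- cross3(v, e); s <- sqrt(sum(k^2)); k <- k / s
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  Rm <- diag(3) + s * K + (1 - c_) * (K %*% K)
  xyz %*% t(Rm)
}
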