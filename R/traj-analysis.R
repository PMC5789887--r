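# Trajectory-derived observables: incoherent intermediate scattering
# function with orientation averaging, three-process decay decomposition,
# C-H bond order parameters and gauche/trans dihedral statistics.

#' Labelled particle trajectory
#'
#' @param positions numeric array `(n_frames, n_atoms, 3)` of unwrapped
#'   coordinates (angstrom).
#' @param dt frame spacing (ps), > 0.
#' @param labels data.frame with one row per atom; recognised columns:
#'   `role` ("C"/"H"), `chain`, `carbon_index`, `bonded_to` (atom index of
#'   the carbon an H is attached to), `region` ("head"/"tail").
#' @param box periodic box lengths (angstrom), length 3; `Inf` for open
#'   boundaries.
#' @param normal_axis index (1-3) of the bilayer normal, default 3 (z).
#' @return List of class `trajectory_bundle`.
#' @export
trajectory_bundle <- function(positions, dt, labels = NULL,
                              box = c(Inf, Inf, Inf), normal_axis = 3L) {
  stopifnot(length(dim(positions)) == 3, dim(positions)[3] == 3,
            dim(positions)[1] >= 2, dt > 0, normal_axis %in% 1:3)
  n_atoms <- dim(positions)[2]
  if (is.null(labels))
    labels <- data.frame(role = rep("H", n_atoms), chain = seq_len(n_atoms),
                         carbon_index = NA_integer_, bonded_to = NA_integer_)
  stopifnot(nrow(labels) == n_atoms)
  structure(list(positions = positions, dt = dt, labels = labels,
                 box = box, normal_axis = as.integer(normal_axis)),
            class = "trajectory_bundle")
}

#' @export
print.trajectory_bundle <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<trajectory_bundle> %d frames x %d atoms, dt = %g ps\n",
              d[1], d[2], x$dt))
  invisible(x)
}

#' Incoherent intermediate scattering function from a trajectory
#'
#' \eqn{I(Q,t) = \overline{\langle e^{i Q\cdot(r(t_0+t)-r(t_0))}\rangle}}
#' averaged over atoms and sliding time origins.  The orientation average
#' over Q directions is applied analytically: `"powder"` (isotropic 3D)
#' gives \eqn{\sin(Qd)/(Qd)} of the displacement magnitude; `"in_plane"`
#' averages Q over the membrane plane, giving \eqn{J_0(Q d_\parallel)}
#' of the in-plane displacement — the natural choice when isolating
#' lateral motion.  Standard errors come from the origin-block variance.
#'
#' @param traj a [trajectory_bundle()] with unwrapped coordinates.
#' @param q momentum transfers (1/angstrom), vectorized.
#' @param atoms indices of atoms to include (default: all, or all `role ==
#'   "H"` atoms when labels carry roles).
#' @param max_lag largest lag in frames; `max_lag * dt` must fit in the
#'   trajectory span.
#' @param n_origins number of sliding time origins (default: 50% overlap).
#' @param orientation `"powder"` or `"in_plane"`.
#' @return data.frame with columns `q`, `t_ps`, `isf`, `stderr`.
#' @export
compute_isf <- function(traj, q, atoms = NULL, max_lag = NULL,
                        n_origins = NULL,
                        orientation = c("powder", "in_plane")) {
  orientation <- match.arg(orientation)
  pos <- traj$positions
  n_frames <- dim(pos)[1]
  if (is.null(max_lag)) max_lag <- n_frames - 1L
  if (max_lag >= n_frames)
    stop("max_lag * dt exceeds the trajectory span")
  if (is.null(atoms)) {
    atoms <- if ("role" %in% names(traj$labels) &&
                 any(traj$labels$role == "H"))
      which(traj$labels$role == "H") else seq_len(dim(pos)[2])
  }
  # wrapped-coordinate guard: single-frame jumps beyond half the box
  finite_box <- is.finite(traj$box)
  if (any(finite_box)) {
    step <- abs(pos[-1, atoms, , drop = FALSE] -
                  pos[-n_frames, atoms, , drop = FALSE])
    for (ax in which(finite_box))
      if (any(step[, , ax] > traj$box[ax] / 2))
        stop("per-frame jumps exceed box/2: coordinates look wrapped; unwrap first")
  }
  if (is.null(n_origins))
    n_origins <- max(1L, floor((n_frames - max_lag) / max(1, max_lag %/% 2)))
  origins <- unique(round(seq(1, n_frames - max_lag, length.out = n_origins)))
  lags <- 0:max_lag
  plane <- setdiff(1:3, traj$normal_axis)
  out <- vector("list", length(q))
  for (iq in seq_along(q)) {
    Q <- q[iq]
    per_origin <- matrix(NA_real_, nrow = length(origins),
                         ncol = length(lags))
    for (io in seq_along(origins)) {
      t0 <- origins[io]
      r0 <- pos[t0, atoms, , drop = FALSE]
      for (il in seq_along(lags)) {
        lag <- lags[il]
        d <- pos[t0 + lag, atoms, , drop = FALSE] - r0
        if (orientation == "powder") {
          dm <- sqrt(d[1, , 1]^2 + d[1, , 2]^2 + d[1, , 3]^2)
          x <- Q * dm
          v <- ifelse(x < 1e-10, 1, sin(x) / x)
        } else {
          dm <- sqrt(d[1, , plane[1]]^2 + d[1, , plane[2]]^2)
          v <- besselJ(Q * dm, 0)
        }
        per_origin[io, il] <- mean(v)
      }
    }
    m <- colMeans(per_origin)
    se <- if (length(origins) > 1)
      apply(per_origin, 2, stats::sd) / sqrt(length(origins))
    else rep(NA_real_, length(lags))
    out[[iq]] <- data.frame(q = Q, t_ps = lags * traj$dt, isf = m,
                            stderr = se)
  }
  do.call(rbind, out)
}

#' Three-process decomposition of an intermediate scattering function
#'
#' Fits \eqn{I(Q,t) = e^{-\Gamma_{lat} t}\,[A_1 + (1-A_1)e^{-\Gamma_{int} t}]
#' \,[A_2 + (1-A_2)e^{-\Gamma_{fast} t}]} by bounded least squares with the
#' rate ordering \eqn{\Gamma_{fast} > \Gamma_{int} > \Gamma_{lat} \ge 0}
#' enforced through an additive parameterization.  Rates are in 1/ps
#' (multiply by hbar = 0.65821 meV.ps for meV).
#'
#' @param t_ps lag times (ps).
#' @param isf ISF values.
#' @param stderr optional uncertainties (weights 1/stderr).
#' @param n_starts,seed multi-start control.
#' @param plateau_tol plateau fractions below this are treated as zero:
#'   the factor is then a pure exponential, degenerate with the lateral
#'   envelope, and its rate is folded into `Gamma_lat` (flagged).
#' @return List with `A1`, `A2`, `Gamma_lat`, `Gamma_int`, `Gamma_fast`
#'   (1/ps), `fitted`, `flags` (degeneracy/unidentifiability markers).
#' @export
fit_isf_three_process <- function(t_ps, isf, stderr = NULL,
                                  n_starts = 16L, seed = 1L,
                                  plateau_tol = 0.01) {
  stopifnot(length(t_ps) == length(isf))
  w <- if (is.null(stderr) || !all(stderr > 0)) rep(1, length(isf))
  else 1 / stderr
  model <- function(th) {
    A1 <- th[1]; A2 <- th[2]
    gl <- th[3]; gi <- th[3] + th[4]; gf <- th[3] + th[4] + th[5]
    exp(-gl * t_ps) * (A1 + (1 - A1) * exp(-gi * t_ps)) *
      (A2 + (1 - A2) * exp(-gf * t_ps))
  }
  resid_fn <- function(th) (model(th) - isf) * w
  lower <- c(0, 0, 0, 1e-8, 1e-8)
  upper <- c(1, 1, 10, 50, 500)
  # heuristic: terminal slope for the slowest rate
  tail_n <- max(3, length(t_ps) %/% 4)
  it <- order(t_ps, decreasing = TRUE)[seq_len(tail_n)]
  pos <- isf[it] > 0
  gl0 <- if (sum(pos) >= 2) {
    sl <- try(-stats::coef(stats::lm(log(isf[it][pos]) ~ t_ps[it][pos]))[2],
              silent = TRUE)
    if (inherits(sl, "try-error") || !is.finite(sl) || sl <= 0) 1e-3
    else as.numeric(sl)
  } else 1e-3
  # second rate scale: the 1/e crossing time (robust when the curve has
  # fully decayed inside the window and the tail is noise-dominated)
  ie <- which(isf < exp(-1))[1]
  gl0e <- if (!is.na(ie) && t_ps[ie] > 0) 1 / t_ps[ie] else gl0
  heur <- c(0.6, 0.8, gl0, gl0 * 20, gl0 * 400)
  # canonical starts cover the degenerate limits: a single exponential
  # (both plateaus ~1, at either rate scale) and a two-process curve
  canon <- rbind(heur,
                 c(0.999, 0.999, gl0, gl0 * 20, gl0 * 400),
                 c(0.999, 0.999, gl0e, gl0e * 20, gl0e * 400),
                 c(0.6, 0.999, gl0e, gl0e * 20, gl0e * 400))
  starts <- with_local_seed(seed, {
    s <- canon[rep(seq_len(nrow(canon)), length.out = max(n_starts, 4)), ,
               drop = FALSE]
    if (nrow(s) > 4) for (k in 5:nrow(s)) {
      s[k, 1:2] <- stats::runif(2, 0.1, 0.95)
      s[k, 3] <- gl0 * exp(stats::runif(1, -1.5, 1.5))
      s[k, 4] <- s[k, 3] * exp(stats::runif(1, log(3), log(300)))
      s[k, 5] <- s[k, 4] * exp(stats::runif(1, log(3), log(300)))
    }
    s
  })
  fit <- multistart_lm(resid_fn, starts, lower, upper, maxiter = 400)
  th <- fit$par
  gl <- th[3]; gi <- th[3] + th[4]; gf <- th[3] + th[4] + th[5]
  flags <- character(0)
  if (th[1] > 1 - 1e-4)
    flags <- c(flags, "A1_at_1_Gamma_int_unidentifiable")
  if (th[2] > 1 - 1e-4)
    flags <- c(flags, "A2_at_1_Gamma_fast_unidentifiable")
  # vanishing plateau fractions make factors pure exponentials, which are
  # degenerate with the leading lateral decay: fold the merged rate back
  # into Gamma_lat so the slowest observable decay is always reported
  # there (a plateau below plateau_tol is invisible at realistic noise)
  if (th[2] < plateau_tol) {
    gl <- gl + gf
    flags <- c(flags, "A2_near_0_Gamma_fast_unidentifiable")
  }
  if (th[1] < plateau_tol) {
    gl <- gl + gi
    flags <- c(flags, "A1_near_0_Gamma_int_unidentifiable")
  }
  if (gf < 1.1 * gi &&
      !any(grepl("Gamma_fast_unidentifiable", flags)))
    flags <- c(flags, "rate_collision_int_fast")
  list(A1 = th[1], A2 = th[2], Gamma_lat = gl, Gamma_int = gi,
       Gamma_fast = gf, fitted = model(th), flags = flags,
       deviance = fit$deviance)
}

# ---------------------------------------------------------------------------
# geometry helpers

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points (IUPAC sign convention)
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return Angle in degrees in (-180, 180\]; `NA` for colinear triplets.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) return(NA_real_)
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- cross3(n1, b2n)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' C-H bond order parameter profile relative to the bilayer normal
#'
#' \eqn{S_{CH}^i = \tfrac12 [3\langle\cos^2\theta_i\rangle - 1]} where
#' \eqn{\theta_i} is the angle between the C-H bond of carbon `i` and the
#' normal axis; averaged over molecules, hydrogens and frames.  Bounds are
#' exact: 1 for bonds parallel to the normal, -0.5 for perpendicular,
#' 0 for isotropic orientations.
#'
#' @param traj a [trajectory_bundle()] whose labels identify H atoms and
#'   their bonded carbon (`role`, `bonded_to`, `carbon_index`).
#' @return data.frame with `carbon_index`, `S_CH`, `n_obs`.
#' @export
order_parameter_profile <- function(traj) {
  lb <- traj$labels
  if (!all(c("role", "bonded_to", "carbon_index") %in% names(lb)))
    stop("labels must carry 'role', 'bonded_to' and 'carbon_index' columns")
  h_idx <- which(lb$role == "H" & !is.na(lb$bonded_to))
  if (!length(h_idx)) stop("no H atoms with bond topology found")
  ax <- traj$normal_axis
  pos <- traj$positions
  n_frames <- dim(pos)[1]
  ci <- lb$carbon_index[lb$bonded_to[h_idx]]
  cos2 <- matrix(NA_real_, nrow = n_frames, ncol = length(h_idx))
  for (f in seq_len(n_frames)) {
    v <- pos[f, h_idx, , drop = FALSE][1, , ] -
      pos[f, lb$bonded_to[h_idx], , drop = FALSE][1, , ]
    if (is.null(dim(v))) v <- matrix(v, ncol = 3)
    nrm <- sqrt(rowSums(v^2))
    cos2[f, ] <- (v[, ax] / nrm)^2
  }
  agg <- tapply(colMeans(cos2), ci, mean)
  data.frame(carbon_index = as.integer(names(agg)),
             S_CH = 0.5 * (3 * as.numeric(agg) - 1),
             n_obs = as.integer(table(ci)[names(agg)]) * n_frames)
}

#' Gauche/trans classification of backbone dihedrals
#'
#' Dihedrals are folded to `|phi|` in \[0, 180\] so both signs of gauche
#' count: gauche iff `|phi|` in \[45, 75\], trans iff `|phi|` in
#' \[165, 180\] (a 165--195 degree window maps onto this after folding);
#' everything else is "other".  Colinear triplets are excluded and counted.
#'
#' @param traj a [trajectory_bundle()]; backbone carbons are rows with
#'   `role == "C"`, grouped by `chain` and ordered by `carbon_index`.
#' @param frames frame indices to analyse (default: all).
#' @return List with `per_bond` (data.frame: `bond`, `gauche`, `trans`,
#'   `other`), totals `gauche`, `trans`, `other`, `excluded`, and `ratio`
#'   = gauche/trans.
#' @export
gauche_trans_ratio <- function(traj, frames = NULL) {
  lb <- traj$labels
  if (!all(c("role", "chain", "carbon_index") %in% names(lb)))
    stop("labels must carry 'role', 'chain' and 'carbon_index' columns")
  pos <- traj$positions
  if (is.null(frames)) frames <- seq_len(dim(pos)[1])
  chains <- split(which(lb$role == "C"), lb$chain[lb$role == "C"])
  chains <- lapply(chains, function(ix) ix[order(lb$carbon_index[ix])])
  chains <- chains[vapply(chains, length, 1L) >= 4]
  if (!length(chains)) stop("need at least 4 consecutive backbone atoms")
  res <- list(); excluded <- 0L
  for (f in frames) {
    for (ch in chains) {
      p <- pos[f, ch, , drop = FALSE][1, , ]
      nb <- length(ch) - 3L
      phi <- vapply(seq_len(nb), function(k)
        dihedral_angle(p[k, ], p[k + 1, ], p[k + 2, ], p[k + 3, ]),
        numeric(1))
      bad <- is.na(phi)
      excluded <- excluded + sum(bad)
      res[[length(res) + 1L]] <-
        data.frame(bond = seq_len(nb)[!bad], phi = abs(phi[!bad]))
    }
  }
  all_phi <- do.call(rbind, res)
  cls <- ifelse(all_phi$phi >= 45 & all_phi$phi <= 75, "gauche",
                ifelse(all_phi$phi >= 165, "trans", "other"))
  per_bond <- do.call(rbind, lapply(split(cls, all_phi$bond), function(v)
    data.frame(gauche = sum(v == "gauche"), trans = sum(v == "trans"),
               other = sum(v == "other"))))
  per_bond <- cbind(bond = as.integer(rownames(per_bond)), per_bond)
  rownames(per_bond) <- NULL
  n_g <- sum(cls == "gauche"); n_t <- sum(cls == "trans")
  list(per_bond = per_bond, gauche = n_g, trans = n_t,
       other = sum(cls == "other"), excluded = excluded,
       ratio = if (n_t > 0) n_g / n_t else NaN)
}

#' Lateral diffusivity from ISF decompositions over Q
#'
#' Converts the lateral decay rates (1/ps) to energy half-widths via
#' hbar and delegates to the Fickian fit [fit_fickian()].
#'
#' @param q momentum transfers (1/angstrom), >= 3 points.
#' @param gamma_lat_per_ps lateral decay rates (1/ps) at `q`.
#' @return The [fit_fickian()] result (`D_lat_cm2s` etc.).
#' @export
lateral_diffusivity_from_isf <- function(q, gamma_lat_per_ps) {
  fit_fickian(q, hbar_meV_ps * gamma_lat_per_ps)
}
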