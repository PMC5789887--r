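# Grouped-spectra containers and instrument plumbing: CSV dialect I/O,
# D2O solvent subtraction, and resolution convolution on uniform energy grids.

#' Uniform energy-transfer grid
#'
#' @param values strictly increasing, uniformly spaced energies (meV).
#'   The accessible IRIS window is -0.3 to +1.0 meV.
#' @return Numeric vector of class `energy_grid` with attribute `de`
#'   (grid step).
#' @export
energy_grid <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 3)
  d <- diff(values)
  if (any(d <= 0)) stop("energy grid must be strictly increasing")
  de <- mean(d)
  if (max(abs(d - de)) > 1e-9 * max(abs(values)))
    stop("energy grid must be uniformly spaced")
  if (min(abs(values)) > de + 1e-12)
    stop("energy grid must contain 0 within one grid step")
  structure(as.numeric(values), de = de, class = "energy_grid")
}

#' Default IRIS-like energy grid: -0.3 to +1.0 meV, 1301 points (1 ueV step)
#' @export
default_energy_grid <- function() energy_grid(seq(-0.3, 1.0, length.out = 1301))

#' Single-Q spectrum
#'
#' @param q momentum transfer (1/angstrom).
#' @param energies an [energy_grid()] (or numeric vector passed through it).
#' @param intensity counts-density per energy bin (arbitrary units).
#' @param sigma 1-sigma uncertainties, >= 0, same length.
#' @return List of class `qens_spectrum`.
#' @export
qens_spectrum <- function(q, energies, intensity, sigma) {
  if (!inherits(energies, "energy_grid")) energies <- energy_grid(energies)
  stopifnot(length(intensity) == length(energies),
            length(sigma) == length(energies), all(sigma >= 0))
  structure(list(q = q, energies = energies, intensity = intensity,
                 sigma = sigma), class = "qens_spectrum")
}

#' @export
print.qens_spectrum <- function(x, ...) {
  cat(sprintf("<qens_spectrum> Q = %.3f 1/A, %d bins on [%.3f, %.3f] meV\n",
              x$q, length(x$energies), min(x$energies), max(x$energies)))
  invisible(x)
}

#' Resolution kernel on an energy grid
#'
#' Unit-area (sum * de = 1), non-negative profile centred at E = 0; the
#' numerical FWHM is recorded.
#'
#' @param energies an [energy_grid()] the kernel is tabulated on.
#' @param values non-negative profile values (renormalized to unit area).
#' @return List of class `resolution_kernel` with `energies`, `values`,
#'   `fwhm` (meV).
#' @export
resolution_kernel <- function(energies, values) {
  if (!inherits(energies, "energy_grid")) energies <- energy_grid(energies)
  stopifnot(length(values) == length(energies), all(values >= -1e-12))
  values <- pmax(values, 0)
  de <- attr(energies, "de")
  area <- sum(values) * de
  if (area <= 0) stop("kernel has zero area")
  values <- values / area
  # numerical FWHM about the peak, with linear interpolation of the
  # half-maximum crossings
  pk <- which.max(values)
  half <- values[pk] / 2
  e <- as.numeric(energies)
  il <- suppressWarnings(max(which(values[1:pk] <= half)))
  ir <- pk - 1 + suppressWarnings(min(which(values[pk:length(values)] <= half)))
  fwhm <- if (is.finite(il) && is.finite(ir)) {
    xl <- e[il] + (half - values[il]) * (e[il + 1] - e[il]) /
      (values[il + 1] - values[il])
    xr <- e[ir - 1] + (half - values[ir - 1]) * (e[ir] - e[ir - 1]) /
      (values[ir] - values[ir - 1])
    xr - xl
  } else NA_real_
  structure(list(energies = energies, values = values, fwhm = fwhm),
            class = "resolution_kernel")
}

#' Gaussian resolution kernel (default FWHM 17 ueV, the IRIS PG(002) value)
#'
#' @param energies an [energy_grid()].
#' @param fwhm_meV full width at half maximum (meV); 0.017 by default.
#' @return A [resolution_kernel()].
#' @export
gaussian_resolution_kernel <- function(energies = default_energy_grid(),
                                       fwhm_meV = 0.017) {
  stopifnot(fwhm_meV > 0)
  if (!inherits(energies, "energy_grid")) energies <- energy_grid(energies)
  s <- fwhm_meV / (2 * sqrt(2 * log(2)))
  resolution_kernel(energies, stats::dnorm(as.numeric(energies), 0, s))
}

# ---------------------------------------------------------------------------
# grouped-spectra CSV dialect:
#   # Q=<value> A^-1
#   E_meV,intensity,sigma
#   ...

#' Write grouped spectra to the grouped-CSV dialect
#'
#' One `# Q=<value> A^-1` header per group followed by
#' `E_meV,intensity,sigma` rows at full precision (round-trip exact).
#'
#' @param spectra list of [qens_spectrum()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grouped_spectra <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(sprintf("# Q=%s A^-1", format(sp$q, digits = 17)), con)
    writeLines("E_meV,intensity,sigma", con)
    writeLines(paste(format(as.numeric(sp$energies), digits = 17),
                     format(sp$intensity, digits = 17),
                     format(sp$sigma, digits = 17), sep = ","), con)
  }
  invisible(path)
}

#' Read grouped spectra from the grouped-CSV dialect
#'
#' @param path file written by [write_grouped_spectra()] (or by hand in the
#'   same dialect).
#' @return List of [qens_spectrum()] objects, one per Q group.
#' @export
read_grouped_spectra <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  heads <- grep("^# *Q=", lines)
  if (!length(heads))
    stop(sprintf("%s: no '# Q=' group headers found", path))
  bounds <- c(heads, length(lines) + 1L)
  out <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    i0 <- heads[k]
    qv <- as.numeric(sub("^# *Q= *([-0-9.eE+]+).*$", "\\1", lines[i0]))
    if (!is.finite(qv))
      stop(sprintf("%s:%d: cannot parse Q value", path, i0))
    hdr <- lines[i0 + 1L]
    if (!identical(trimws(hdr), "E_meV,intensity,sigma"))
      stop(sprintf("%s:%d: expected header 'E_meV,intensity,sigma'",
                   path, i0 + 1L))
    body <- lines[(i0 + 2L):(bounds[k + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    m <- do.call(rbind, strsplit(body, ","))
    if (ncol(m) != 3)
      stop(sprintf("%s: group at line %d: expected 3 columns", path, i0))
    e <- as.numeric(m[, 1]); int <- as.numeric(m[, 2]); sg <- as.numeric(m[, 3])
    if (anyNA(e) || anyNA(int) || anyNA(sg))
      stop(sprintf("%s: group at line %d: non-numeric entries", path, i0))
    if (any(diff(e) <= 0))
      stop(sprintf("%s: group at line %d: energy column not strictly increasing",
                   path, i0))
    out[[k]] <- qens_spectrum(qv, energy_grid(e), int, sg)
  }
  out
}

# ---------------------------------------------------------------------------

#' Subtract the solvent contribution from a solution spectrum
#'
#' `I_bl = I_solution - phi * I_D2O` with uncertainties combined in
#' quadrature (`sigma = sqrt(sigma_sol^2 + phi^2 sigma_D2O^2)`).  Negative
#' bins are retained (unbiased least squares); their count is attached as
#' attribute `"n_negative"`.
#'
#' @param solution,solvent [qens_spectrum()] objects on identical Q and
#'   energy grids.
#' @param phi volume fraction of D2O in the solution, in (0, 1\].
#' @return A background-subtracted [qens_spectrum()].
#' @export
subtract_solvent <- function(solution, solvent, phi) {
  stopifnot(phi > 0, phi <= 1)
  if (!isTRUE(all.equal(solution$q, solvent$q)) ||
      length(solution$energies) != length(solvent$energies) ||
      max(abs(as.numeric(solution$energies) - as.numeric(solvent$energies))) > 1e-9)
    stop("solution and solvent spectra must share the same Q and energy grid")
  int <- solution$intensity - phi * solvent$intensity
  sg <- sqrt(solution$sigma^2 + phi^2 * solvent$sigma^2)
  out <- qens_spectrum(solution$q, solution$energies, int, sg)
  attr(out, "n_negative") <- sum(int < 0)
  out
}

#' Default D2O volume fraction for a DODAB dispersion
#'
#' phi = 1 - v_m * c with the DODAB molar volume v_m = M/rho
#' (M = 630.96 g/mol, rho = 0.87 g/cm^3, so v_m = 0.725 L/mol) and the
#' molar concentration `c` of the dispersion; for the 70 mM preparation
#' phi = 0.949.  Override with a measured value where available.
#'
#' @param conc_M molar concentration (mol/L), default 0.070.
#' @param molar_volume_L_per_mol lipid molar volume (L/mol).
#' @return phi in (0, 1].
#' @export
default_solvent_fraction <- function(conc_M = 0.070,
                                     molar_volume_L_per_mol = 0.725) {
  phi <- 1 - conc_M * molar_volume_L_per_mol
  if (phi <= 0 || phi > 1) stop("computed phi outside (0, 1]")
  phi
}

# ---------------------------------------------------------------------------

#' Convolve model values with the resolution kernel
#'
#' Discrete linear convolution times the grid step, centre-aligned: the
#' kernel's E = 0 bin maps onto each model bin.  Both inputs must share the
#' same uniform step; kernels tabulated on a different grid should be
#' re-interpolated first ([interpolate_kernel()]).
#'
#' @param values model spectral density tabulated on `grid`.
#' @param kernel a [resolution_kernel()] whose grid step matches `grid`.
#' @param grid an [energy_grid()] for `values`.
#' @return Convolved values on `grid`.
#' @export
convolve_resolution <- function(values, kernel, grid) {
  if (!inherits(grid, "energy_grid")) grid <- energy_grid(grid)
  de <- attr(grid, "de")
  kde <- attr(kernel$energies, "de")
  if (abs(de - kde) > 1e-9 * de)
    stop("kernel and model grid steps differ; interpolate the kernel first")
  kv <- kernel$values
  i0 <- which.min(abs(as.numeric(kernel$energies)))  # kernel E = 0 index
  n <- length(values)
  full <- stats::convolve(values, rev(kv), type = "open")  # length n + m - 1
  out <- full[(i0):(i0 + n - 1)] * de
  out
}

#' Re-tabulate a resolution kernel onto a new energy grid
#'
#' Linear interpolation followed by renormalization to unit area.
#'
#' @param kernel a [resolution_kernel()].
#' @param grid target [energy_grid()].
#' @return A [resolution_kernel()] on `grid`.
#' @export
interpolate_kernel <- function(kernel, grid) {
  if (!inherits(grid, "energy_grid")) grid <- energy_grid(grid)
  v <- stats::approx(as.numeric(kernel$energies), kernel$values,
                     xout = as.numeric(grid), yleft = 0, yright = 0)$y
  resolution_kernel(grid, v)
}

#' Resolution-convolved spectrum of a spectral mixture
#'
#' The elastic delta convolves analytically into the kernel shape; the
#' quasielastic Lorentzians are evaluated on a grid padded by the kernel
#' half-support and convolved numerically (FFT), so window-edge losses
#' affect only the far Lorentzian tails.
#'
#' @param mix a [lorentzian_mixture()].
#' @param grid target [energy_grid()].
#' @param kernel a [resolution_kernel()] (same grid step as `grid`).
#' @return Spectral density on `grid` (unit total area up to window
#'   truncation).
#' @export
convolved_mixture <- function(mix, grid, kernel) {
  if (!inherits(grid, "energy_grid")) grid <- energy_grid(grid)
  de <- attr(grid, "de")
  e <- as.numeric(grid)
  # elastic part: delta (x) R = kernel shape centred at 0
  out <- if (mix$elastic > 0) {
    mix$elastic * stats::approx(as.numeric(kernel$energies), kernel$values,
                                xout = e, yleft = 0, yright = 0)$y
  } else rep(0, length(e))
  if (length(mix$weights)) {
    kc <- trim_kernel(kernel)
    # pad by kernel half-support on both sides
    npad <- ceiling(length(kc$values) / 2) + 1L
    epad <- c(e[1] - rev(seq_len(npad)) * de, e, e[length(e)] + seq_len(npad) * de)
    qe <- mixture_quasielastic(mix, epad)
    conv <- convolve_resolution(qe, kc, energy_grid(epad))
    out <- out + conv[(npad + 1):(npad + length(e))]
  }
  out
}

# restrict a kernel to its numerically significant support (speeds up FFTs);
# keeps the E = 0 bin centred within the retained window
trim_kernel <- function(kernel, rel_tol = 1e-12) {
  v <- kernel$values
  keep <- which(v > rel_tol * max(v))
  i0 <- which.min(abs(as.numeric(kernel$energies)))
  half <- max(abs(range(keep) - i0)) + 1L
  lo <- max(1L, i0 - half); hi <- min(length(v), i0 + half)
  if (lo == 1L && hi == length(v)) return(kernel)
  resolution_kernel(energy_grid(as.numeric(kernel$energies)[lo:hi]),
                    v[lo:hi])
}
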