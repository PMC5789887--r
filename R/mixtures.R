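# Every incoherent scattering law in this package is, before resolution
# convolution, a delta function at E = 0 plus a finite sum of unit-area
# Lorentzians centred at E = 0.  `lorentzian_mixture` is the common currency:
# an elastic weight plus paired vectors of quasielastic weights and HWHMs.

#' Unit-area Lorentzian spectral density
#'
#' \eqn{L(\Gamma, E) = (1/\pi)\,\Gamma / (\Gamma^2 + E^2)}, the lineshape of
#' an exponentially decaying correlation with HWHM \eqn{\Gamma}.
#'
#' @param e energy transfer (meV), any numeric vector.
#' @param gamma HWHM (meV), strictly positive scalar.
#' @return Spectral density (1/meV) at `e`.
#' @export
lorentzian <- function(e, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("'gamma' must be a positive finite scalar HWHM")
  (gamma / pi) / (gamma^2 + e^2)
}

#' Construct a delta-plus-Lorentzians spectral mixture
#'
#' @param elastic weight of the elastic (delta) component.
#' @param weights quasielastic component weights (may be empty).
#' @param gammas HWHMs (meV) matching `weights`; all > 0.
#' @param q momentum transfer the mixture was built at (bookkeeping).
#' @return Object of class `lorentzian_mixture`.
#' @export
lorentzian_mixture <- function(elastic, weights = numeric(0),
                               gammas = numeric(0), q = NA_real_) {
  stopifnot(length(weights) == length(gammas))
  if (length(gammas) && any(gammas <= 0))
    stop("all quasielastic HWHMs must be positive")
  keep <- weights > 0
  structure(list(elastic = elastic, weights = weights[keep],
                 gammas = gammas[keep], q = q),
            class = "lorentzian_mixture")
}

#' @export
print.lorentzian_mixture <- function(x, ...) {
  cat(sprintf(
    "<lorentzian_mixture> elastic %.4f + %d Lorentzian(s), total weight %.6f\n",
    x$elastic, length(x$weights), mixture_weight(x)))
  invisible(x)
}

#' Total spectral weight of a mixture (should be 1 for a scattering law)
#' @param mix a `lorentzian_mixture`.
#' @return Numeric scalar.
#' @export
mixture_weight <- function(mix) mix$elastic + sum(mix$weights)

#' Evaluate the quasielastic part of a mixture
#'
#' @param mix a `lorentzian_mixture`.
#' @param e energy transfers (meV).
#' @return Quasielastic spectral density at `e` (the delta is excluded).
#' @export
mixture_quasielastic <- function(mix, e) {
  if (!length(mix$weights)) return(rep(0, length(e)))
  # outer over components; vectorized in E
  g <- mix$gammas; w <- mix$weights
  colSums(w * (g / pi) / (g^2 + matrix(e, nrow = length(g),
                                       ncol = length(e), byrow = TRUE)^2))
}

#' Half-width at half-maximum of a multi-Lorentzian quasielastic profile
#'
#' Sums of zero-centred Lorentzians are even and strictly decreasing in |E|,
#' so the half-maximum crossing is unique; it is found by bracketing and
#' `uniroot` at tight tolerance.  No closed form exists once more than one
#' width is present.
#'
#' @param mix a `lorentzian_mixture` with at least one quasielastic component.
#' @param tol absolute root tolerance in meV.
#' @return HWHM (meV) of the elastic-removed profile.
#' @export
mixture_hwhm <- function(mix, tol = 1e-9) {
  if (!length(mix$weights)) stop("mixture has no quasielastic component")
  s0 <- mixture_quasielastic(mix, 0)
  f <- function(e) mixture_quasielastic(mix, e) - s0 / 2
  hi <- max(mix$gammas)
  while (f(hi) > 0) hi <- hi * 2
  lo <- min(mix$gammas) / 2
  while (f(lo) < 0) lo <- lo / 2
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Add a Lorentzian broadening to every component of a mixture
#'
#' Convolution with a Lorentzian of HWHM `gamma` turns the delta into a
#' Lorentzian of HWHM `gamma` and adds `gamma` to every quasielastic HWHM
#' (Lorentzian widths are additive under convolution).
#'
#' @param mix a `lorentzian_mixture`.
#' @param gamma Lorentzian HWHM (meV) to convolve with; `gamma = 0` returns
#'   the mixture unchanged.
#' @return A new `lorentzian_mixture`.
#' @export
mixture_broaden <- function(mix, gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0)
  if (gamma == 0) return(mix)
  lorentzian_mixture(
    elastic = 0,
    weights = c(mix$elastic, mix$weights),
    gammas  = c(gamma, mix$gammas + gamma),
    q = mix$q)
}
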