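# Internal unit system: lengths in angstrom (A), times in ps, energies in meV,
# momentum transfer Q in 1/A.  Diffusivities are carried in A^2/ps internally
# and reported in cm^2/s (1 A^2/ps = 1e-4 cm^2/s).

#' Physical constants used throughout the package
#'
#' `hbar_meV_ps` is the reduced Planck constant expressed in meV.ps, the
#' natural unit for converting residence times (ps) and diffusive rates
#' (1/ps) into quasielastic half-widths (meV): a Lorentzian of correlation
#' rate `1/tau` (1/ps) has HWHM `hbar_meV_ps / tau` meV.
#' `rgas_kcal_molK` is the molar gas constant in kcal/(mol K), used in
#' Arrhenius fits.
#'
#' @format Named numeric scalars.
#' @export
hbar_meV_ps <- 0.65821

#' @rdname hbar_meV_ps
#' @export
rgas_kcal_molK <- 1.98720e-3

#' Convert a diffusion coefficient between cm^2/s and A^2/ps
#'
#' @param d numeric vector of diffusivities.
#' @return Converted diffusivities.
#' @export
cm2s_to_A2ps <- function(d) d * 1e4

#' @rdname cm2s_to_A2ps
#' @export
A2ps_to_cm2s <- function(d) d * 1e-4

#' Count hydrogen atoms in a simple molecular-fragment formula
#'
#' Parses fragments like `"C18H37"` or `"(CH3)2"`: element symbols with
#' optional counts, with one optional level of parenthesised repetition.
#' Only the hydrogen count is returned.
#'
#' @param formula character scalar, e.g. `"C18H37"`.
#' @return Integer number of H atoms in the fragment.
#' @examples
#' count_hydrogens("C18H37")   # 37
#' count_hydrogens("(CH3)2")   # 6
#' @export
count_hydrogens <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  count_flat <- function(s) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
    if (m[1] == -1) return(0L)
    toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
    n <- 0L
    for (tk in toks) {
      el <- gsub("[0-9]", "", tk)
      cnt <- gsub("[^0-9]", "", tk)
      cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
      if (el == "H") n <- n + cnt
    }
    n
  }
  total <- 0L
  rest <- formula
  # expand (...)k groups
  repeat {
    m <- regexpr("\\(([^()]*)\\)([0-9]*)", rest)
    if (m == -1) break
    grp <- regmatches(rest, m)
    inner <- sub("\\(([^()]*)\\)([0-9]*)", "\\1", grp)
    mult <- sub("\\(([^()]*)\\)([0-9]*)", "\\2", grp)
    mult <- if (nzchar(mult)) as.integer(mult) else 1L
    total <- total + mult * count_flat(inner)
    regmatches(rest, m) <- ""
  }
  total + count_flat(rest)
}

#' Head/tail hydrogen partitioning of a two-chain quaternary ammonium lipid
#'
#' For DODAB, (C18H37)2N(CH3)2 Br, the exchange-inert hydrogens split into
#' 6 head-group hydrogens (two N-methyls) and 74 alkyl-chain hydrogens
#' (two octadecyl chains), giving P_h = 6/80 and P_t = 74/80.  The counts
#' are computed from the fragment formulas, not hard-coded.
#'
#' @param head_formula,tail_formula fragment formulas for the head-group
#'   hydrogens and the alkyl-tail hydrogens.
#' @return List with integer counts `n_head`, `n_tail` and fractions
#'   `P_h`, `P_t` (summing to 1).
#' @examples
#' hydrogen_partition()  # DODAB defaults: P_h = 0.075, P_t = 0.925
#' @export
hydrogen_partition <- function(head_formula = "(CH3)2",
                               tail_formula = "(C18H37)2") {
  n_h <- count_hydrogens(head_formula)
  n_t <- count_hydrogens(tail_formula)
  if (n_h + n_t <= 0) stop("no hydrogens found in the given formulas")
  list(n_head = n_h, n_tail = n_t,
       P_h = n_h / (n_h + n_t), P_t = n_t / (n_h + n_t))
}
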