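# Fixed elastic window scan (FEWS) analysis: normalization to a base
# temperature, mean-squared-displacement extraction under the Gaussian
# approximation, and change-point detection of dynamical transitions.

#' Elastic-intensity scan series
#'
#' @param data data.frame with columns `T_K`, `cycle` ("heating"/"cooling"),
#'   `Q_invA`, `I_el` (> 0) and optionally `sigma`.
#' @param T_min base temperature (K) the scans are normalized to (the
#'   lowest measured point, 10 K on IRIS).
#' @return data.frame of class `elastic_scan`.
#' @export
elastic_scan <- function(data, T_min = min(data$T_K)) {
  need <- c("T_K", "cycle", "Q_invA", "I_el")
  if (!all(need %in% names(data)))
    stop("elastic scan needs columns: ", paste(need, collapse = ", "))
  if (!all(data$I_el > 0)) stop("elastic intensities must be positive")
  if (!all(data$cycle %in% c("heating", "cooling")))
    stop("cycle must be 'heating' or 'cooling'")
  if (is.null(data$sigma)) data$sigma <- 0
  structure(as.data.frame(data), T_min = T_min, class = c("elastic_scan",
                                                          "data.frame"))
}

#' Read an elastic scan from CSV (columns T_K,cycle,Q_invA,I_el[,sigma])
#' @param path CSV file path.
#' @return An [elastic_scan()].
#' @export
read_elastic_scan <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  elastic_scan(utils::read.csv(path))
}

#' Mean-squared displacement from the Q-dependence of elastic intensity
#'
#' Under the Gaussian approximation,
#' \eqn{\ln[I_{el}(Q,T)/I_{el}(Q,T_{min})] = -\langle u^2\rangle Q^2/6};
#' a weighted linear fit of the log-ratio against Q^2 over `q_lo`--`q_hi`
#' yields the MSD at each temperature from the slope.  The intercept is
#' left free to absorb normalization drift (it reduces to the pure Gaussian
#' form when ~0).  Bins with non-positive ratio are excluded with a warning.
#'
#' @param scan an [elastic_scan()] containing the base temperature.
#' @param cycle which cycle to analyse.
#' @param q_lo,q_hi Q fit window (1/angstrom); 0.5--0.95 restricts to the
#'   low-Q regime where the Gaussian approximation holds.
#' @param base data.frame of base-temperature intensities per Q; defaults to
#'   the rows of `scan` at its `T_min` attribute (any cycle).
#' @return data.frame with `T_K`, `u2` (angstrom^2), `stderr`, `n_bins`.
#' @export
fit_msd <- function(scan, cycle = "heating", q_lo = 0.5, q_hi = 0.95,
                    base = NULL) {
  T_min <- attr(scan, "T_min")
  if (is.null(base)) {
    base <- scan[scan$T_K == T_min, c("Q_invA", "I_el", "sigma")]
    if (!nrow(base)) stop("no base-temperature rows found in scan")
  }
  sub <- scan[scan$cycle == cycle & scan$T_K != T_min &
                scan$Q_invA >= q_lo & scan$Q_invA <= q_hi, ]
  temps <- sort(unique(sub$T_K))
  res <- lapply(temps, function(tt) {
    rows <- sub[sub$T_K == tt, ]
    m <- merge(rows, base, by = "Q_invA", suffixes = c("", "_base"))
    ratio <- m$I_el / m$I_el_base
    ok <- ratio > 0
    if (any(!ok))
      warning(sprintf("T = %g K: %d non-positive intensity ratio(s) excluded",
                      tt, sum(!ok)))
    m <- m[ok, ]; ratio <- ratio[ok]
    if (nrow(m) < 3)
      stop(sprintf("T = %g K: fewer than 3 usable Q bins in [%g, %g]",
                   tt, q_lo, q_hi))
    y <- log(ratio)
    # propagated sigma of the log ratio; fall back to equal weights
    sy <- sqrt((m$sigma / m$I_el)^2 + (m$sigma_base / m$I_el_base)^2)
    w <- if (all(sy > 0)) 1 / sy^2 else rep(1, nrow(m))
    # weighted straight-line fit, free intercept (closed form)
    x <- m$Q_invA^2
    xb <- sum(w * x) / sum(w); yb <- sum(w * y) / sum(w)
    sxx <- sum(w * (x - xb)^2)
    sl <- sum(w * (x - xb) * (y - yb)) / sxx
    res <- y - yb - sl * (x - xb)
    dof <- max(nrow(m) - 2, 1)
    se <- sqrt(max(sum(w * res^2) / dof, 0) / sxx)
    data.frame(T_K = tt, u2 = -6 * sl, stderr = 6 * se, n_bins = nrow(m))
  })
  out <- do.call(rbind, res)
  attr(out, "q_range") <- c(q_lo, q_hi)
  out
}

#' Q-averaged elastic intensity versus temperature
#'
#' Unweighted mean over the Q bins inside the window (0.5 < Q < 1.8 by
#' default, the instrument range).
#'
#' @param scan an [elastic_scan()].
#' @param cycle which cycle.
#' @param q_lo,q_hi averaging window (1/angstrom).
#' @return data.frame with `T_K`, `I_el` sorted by temperature.
#' @export
q_average_elastic <- function(scan, cycle = "heating", q_lo = 0.5, q_hi = 1.8) {
  sub <- scan[scan$cycle == cycle & scan$Q_invA >= q_lo & scan$Q_invA <= q_hi, ]
  if (!nrow(sub)) stop("no Q bins inside the averaging window")
  agg <- stats::aggregate(I_el ~ T_K, data = sub, FUN = mean)
  agg[order(agg$T_K), ]
}

#' Detect dynamical transitions as change-points of a piecewise-linear model
#'
#' Fits free piecewise-linear segments (each with its own slope and
#' intercept, so both slope kinks and intensity steps are representable)
#' with 0 to `max_breaks` breakpoints; the segmentation minimizing the
#' residual sum of squares is chosen per breakpoint count by dynamic
#' programming, and the number of breakpoints by BIC.  Invariant under
#' affine rescaling of the intensity.
#'
#' @param temperature,intensity numeric vectors (>= 7 points).
#' @param max_breaks maximum number of change-points (default 3).
#' @param min_seg minimum points per segment.
#' @return Numeric vector of transition temperatures (midpoints between the
#'   segments' boundary samples), possibly empty; attribute `"k"` holds the
#'   selected breakpoint count.
#' @export
detect_transitions <- function(temperature, intensity, max_breaks = 3L,
                               min_seg = 3L) {
  stopifnot(length(temperature) == length(intensity))
  o <- order(temperature)
  tt <- temperature[o]; yy <- intensity[o]
  n <- length(tt)
  if (n < 7) stop("need at least 7 temperature points")
  if (n < (max_breaks + 1) * min_seg)
    max_breaks <- max(0L, n %/% min_seg - 1L)
  # segment cost: RSS of a straight-line fit on points i..j
  cost <- matrix(Inf, n, n)
  for (i in 1:(n - min_seg + 1)) {
    for (j in (i + min_seg - 1):n) {
      xs <- tt[i:j]; ys <- yy[i:j]
      mx <- mean(xs); my <- mean(ys)
      sxx <- sum((xs - mx)^2)
      b <- if (sxx > 0) sum((xs - mx) * (ys - my)) / sxx else 0
      cost[i, j] <- sum((ys - my - b * (xs - mx))^2)
    }
  }
  # dynamic programming over number of segments
  best <- list()
  dp_prev <- cost[1, ]                     # 1 segment ending at j
  choice <- list(matrix(NA_integer_, 1, n))
  dp <- list(dp_prev)
  for (s in 2:(max_breaks + 1)) {
    dpc <- rep(Inf, n)
    ch <- rep(NA_integer_, n)
    for (j in (s * min_seg):n) {
      ks <- ((s - 1) * min_seg):(j - min_seg)
      vals <- dp[[s - 1]][ks] + cost[ks + 1, j]
      m <- which.min(vals)
      dpc[j] <- vals[m]; ch[j] <- ks[m]
    }
    dp[[s]] <- dpc
    choice[[s]] <- ch
  }
  # BIC: n log(RSS/n) + p log(n); p = 2 per segment + 1 per breakpoint
  bic <- vapply(1:(max_breaks + 1), function(s) {
    rss <- max(dp[[s]][n], .Machine$double.eps)
    n * log(rss / n) + (3 * s - 1) * log(n)
  }, numeric(1))
  s_best <- which.min(bic)
  # backtrack breakpoints
  brk <- integer(0)
  j <- n
  if (s_best > 1) {
    for (s in s_best:2) {
      k <- choice[[s]][j]
      brk <- c(k, brk)
      j <- k
    }
  }
  out <- if (length(brk)) (tt[brk] + tt[brk + 1]) / 2 else numeric(0)
  structure(sort(out), k = s_best - 1L)
}
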