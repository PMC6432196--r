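#' Micro-canonical curves from a density of states
#'
#' From the micro-canonical entropy \eqn{S(E) = \ln g(E)} on the unit-spaced
#' integer energy grid, computes the inverse micro-canonical temperature
#' \eqn{\beta_\mu(E) = dS/dE} and its derivative
#' \eqn{\gamma(E) = d^2 S/dE^2} by central differences:
#' \eqn{\beta_\mu(E) = (S(E+1) - S(E-1))/2},
#' \eqn{\gamma(E) = S(E+1) - 2 S(E) + S(E-1)} (exact for quadratics).
#' A local maximum of \eqn{\gamma(E)} above zero signals a first-order
#' pseudo transition (convex intruder in S); below zero, a second-order one.
#'
#' Unpopulated interior levels are refused by default: silently
#' interpolating across gaps can fabricate transitions.  Set
#' `allow_gaps = TRUE` to restrict the stencil to the populated contiguous
#' blocks instead.
#'
#' @param dos A [dos_estimate()] (only levels with visits > 0 are used; a
#'   table loaded from disk with all visits 0 is used as-is).
#' @param smoothing `NULL` (default: none) or `list(window, order)` for
#'   Savitzky-Golay smoothing of S(E) before differentiating; the smoothing
#'   descriptor is stored, never applied silently.
#' @param allow_gaps Tolerate unpopulated interior levels (see above).
#' @return A `micro_curves` data frame (energy, S, beta_micro, gamma_E;
#'   derivative columns are NA at the grid ends) with attributes `smoothing`.
#' @export
micro_curves <- function(dos, smoothing = NULL, allow_gaps = FALSE) {
  pop <- if (any(dos$visits > 0)) dos[dos$visits > 0, ] else dos
  e <- pop$energy
  if (length(e) < 5L) stop("need at least 5 populated energy levels")
  if (any(diff(e) != 1)) {
    if (!allow_gaps)
      stop("unpopulated interior energy levels at E = ",
           paste(setdiff(seq(min(e), max(e)), e), collapse = ", "),
           "; sample longer or set allow_gaps = TRUE")
  }
  s <- pop$ln_g
  if (!is.null(smoothing)) {
    if (!all(c("window", "order") %in% names(smoothing)))
      stop("smoothing must be list(window, order)")
    s <- as.numeric(signal::sgolayfilt(s, p = smoothing$order,
                                       n = smoothing$window))
  }
  m <- length(e)
  beta <- gam <- rep(NA_real_, m)
  idx <- 2:(m - 1)
  ok <- (e[idx + 1] - e[idx] == 1) & (e[idx] - e[idx - 1] == 1)
  idx <- idx[ok]
  beta[idx] <- (s[idx + 1] - s[idx - 1]) / 2
  gam[idx] <- s[idx + 1] - 2 * s[idx] + s[idx - 1]
  out <- data.frame(energy = e, S = s, beta_micro = beta, gamma_E = gam)
  class(out) <- c("micro_curves", "data.frame")
  attr(out, "smoothing") <- smoothing
  out
}

# interior local maxima of y with prominence above frac of the curve range;
# ties broken toward lower x
find_peaks <- function(x, y, prominence_frac = 0.05) {
  ok <- is.finite(y)
  x <- x[ok]; y <- y[ok]
  m <- length(y)
  if (m < 3L) return(data.frame(x = numeric(0), y = numeric(0)))
  i <- 2:(m - 1)
  is_max <- y[i] >= y[i - 1] & y[i] > y[i + 1]
  cand <- i[is_max]
  if (!length(cand)) return(data.frame(x = numeric(0), y = numeric(0)))
  rng <- diff(range(y))
  thr <- prominence_frac * rng
  keep <- vapply(cand, function(k) {
    # prominence: height above the higher of the two flanking minima
    left <- min(y[1:k]); right <- min(y[k:m])
    (y[k] - max(left, right)) >= thr
  }, logical(1))
  cand <- cand[keep]
  data.frame(x = x[cand], y = y[cand])
}

#' Classify pseudo transitions from the micro-canonical curves
#'
#' Finds interior local maxima of \eqn{\gamma(E) = d^2S/dE^2} whose
#' prominence exceeds `peak_prominence` (as a fraction of the curve range)
#' and classifies each by the sign of the peak value: above zero, first
#' order; below zero, second order.
#'
#' @param curves A [micro_curves()] result.
#' @param peak_prominence Minimal peak prominence as a fraction of the
#'   \eqn{\gamma(E)} range; default 0.05.
#' @return A `transition_records` data frame (location, order, diagnostic,
#'   value); zero rows when no peak qualifies.
#' @export
classify_transitions_micro <- function(curves, peak_prominence = 0.05) {
  pk <- find_peaks(curves$energy, curves$gamma_E, peak_prominence)
  out <- data.frame(
    location = pk$x,
    order = ifelse(pk$y > 0, "first", "second"),
    diagnostic = rep("gamma_peak_sign", nrow(pk)),
    value = pk$y,
    stringsAsFactors = FALSE)
  class(out) <- c("transition_records", "data.frame")
  out
}

# log-sum-exp with the max-shift trick; no raw partition function is formed
lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

dos_levels <- function(dos) {
  pop <- if (any(dos$visits > 0)) dos[dos$visits > 0, ] else dos
  list(e = pop$energy, lng = pop$ln_g)
}

#' Log canonical partition function
#'
#' \eqn{\ln Z(T) = \ln \sum_E g(E) e^{-E/T}} over the populated levels,
#' evaluated with the log-sum-exp shift so it is finite for every T > 0.
#' Temperatures are in units of \eqn{\epsilon / k_B}.
#'
#' @param dos A [dos_estimate()].
#' @param temp Temperature(s) > 0.
#' @return \eqn{\ln Z} at each temperature.
#' @export
log_partition_function <- function(dos, temp) {
  if (any(temp <= 0)) stop("temperature must be > 0")
  lv <- dos_levels(dos)
  vapply(temp, function(tt) lse(lv$lng - lv$e / tt), numeric(1))
}

canonical_weights <- function(lng, e, tt) {
  lw <- lng - e / tt
  exp(lw - lse(lw))
}

#' Canonical mean energy
#'
#' \eqn{\langle E \rangle(T)} from the Boltzmann-weighted density of states.
#'
#' @inheritParams log_partition_function
#' @return Mean energy at each temperature.
#' @export
mean_energy <- function(dos, temp) {
  if (any(temp <= 0)) stop("temperature must be > 0")
  lv <- dos_levels(dos)
  vapply(temp, function(tt) sum(canonical_weights(lv$lng, lv$e, tt) * lv$e),
         numeric(1))
}

#' Canonical specific heat
#'
#' \eqn{C_N(T)}.  The default `"fluctuation"` method uses the variance form
#' \eqn{(\langle E^2 \rangle - \langle E \rangle^2)/T^2}, which is
#' non-negative by construction.  The `"derivative"` method evaluates the
#' equivalent temperature-derivative expression
#' \eqn{C_N = 2 T\, Z'/Z + T^2 Z''/Z - T^2 (Z'/Z)^2
#'        = 2 T\, (\ln Z)' + T^2 (\ln Z)''}
#' by central finite differences of \eqn{\ln Z}; the two agree wherever both
#' are numerically stable and the agreement is used as a self-check in the
#' test-suite.
#'
#' @inheritParams log_partition_function
#' @param method `"fluctuation"` (default) or `"derivative"`.
#' @param dT Step for the finite-difference derivative method.
#' @return \eqn{C_N(T)} at each temperature (units of \eqn{k_B}).
#' @export
specific_heat <- function(dos, temp, method = c("fluctuation", "derivative"),
                          dT = 1e-4) {
  if (any(temp <= 0)) stop("temperature must be > 0")
  method <- match.arg(method)
  lv <- dos_levels(dos)
  if (method == "fluctuation") {
    vapply(temp, function(tt) {
      w <- canonical_weights(lv$lng, lv$e, tt)
      e1 <- sum(w * lv$e)
      (sum(w * lv$e^2) - e1^2) / tt^2
    }, numeric(1))
  } else {
    vapply(temp, function(tt) {
      h <- min(dT, tt / 4)
      lz <- log_partition_function(dos, c(tt - h, tt, tt + h))
      d1 <- (lz[3] - lz[1]) / (2 * h)
      d2 <- (lz[3] - 2 * lz[2] + lz[1]) / h^2
      2 * tt * d1 + tt^2 * d2
    }, numeric(1))
  }
}

#' Canonical average of an energy-resolved observable
#'
#' Reweights the per-energy arithmetic means \eqn{\bar O(E)} into the
#' canonical ensemble, \eqn{\langle O \rangle(T) = \sum_E \bar O(E) g(E)
#' e^{-E/T} / Z(T)}, in log space.  Levels carrying Boltzmann weight but no
#' observable samples trigger a warning and a renormalization over the
#' covered levels when their total weight exceeds `missing_tol`.
#'
#' @param obs An `energy_observables` table.
#' @param dos The matching [dos_estimate()].
#' @param temp Temperature(s) > 0.
#' @param field `"rg2"` (default) for \eqn{R_g^2}, or `c(i, j)` for the
#'   (i, j) contact frequency, giving the temperature-dependent contact
#'   probability.
#' @param missing_tol Weight on levels without observable coverage above
#'   which a warning is issued; default 1e-6.
#' @return The canonical average at each temperature.
#' @export
canonical_average <- function(obs, dos, temp, field = "rg2",
                              missing_tol = 1e-6) {
  if (any(temp <= 0)) stop("temperature must be > 0")
  lv <- dos_levels(dos)
  covered <- obs$energy[obs$count > 0]
  if (identical(field, "rg2")) {
    oval <- obs$rg2_mean[match(lv$e, obs$energy)]
  } else if (is.numeric(field) && length(field) == 2L) {
    cf <- attr(obs, "contact_freq")
    oval <- vapply(lv$e, function(ee) {
      m <- cf[[as.character(ee)]]
      if (is.null(m)) NA_real_ else m[field[1], field[2]]
    }, numeric(1))
  } else stop("field must be \"rg2\" or an index pair c(i, j)")
  have <- lv$e %in% covered & !is.na(oval)
  vapply(temp, function(tt) {
    w <- canonical_weights(lv$lng, lv$e, tt)
    wm <- sum(w[!have])
    if (wm > missing_tol)
      warning(sprintf(paste0("%.3g of the Boltzmann weight at T = %g lies on",
                             " levels without observable samples; ",
                             "renormalizing over covered levels"), wm, tt))
    sum(w[have] * oval[have]) / sum(w[have])
  }, numeric(1))
}

#' Canonical energy distribution
#'
#' \eqn{P(E | T) \propto g(E) e^{-E/T}}, normalized to 1 over the populated
#' levels.  A double-peaked \eqn{P(E|T)} at the transition temperature is
#' the canonical signature of a first-order pseudo transition.
#'
#' @inheritParams log_partition_function
#' @param temp A single temperature > 0.
#' @return Data frame (energy, prob).
#' @export
energy_distribution <- function(dos, temp) {
  if (length(temp) != 1L || temp <= 0) stop("temp must be a single value > 0")
  lv <- dos_levels(dos)
  lw <- lv$lng - lv$e / temp
  data.frame(energy = lv$e, prob = exp(lw - lse(lw)))
}

#' Detect bimodality of an energy distribution
#'
#' Two interior local maxima separated by a minimum at most `depth_factor`
#' times the smaller peak height qualify as bimodal.
#'
#' @param pdist Data frame (energy, prob) from [energy_distribution()].
#' @param depth_factor Valley depth rule in (0, 1\]; default 0.9
#'   (valley must drop at least 10\% below the smaller peak).
#' @param prominence_frac Peak prominence threshold as in [find_peaks()].
#' @return List: `is_bimodal`, `peaks` (energies of the qualifying maxima).
#' @export
detect_bimodality <- function(pdist, depth_factor = 0.9,
                              prominence_frac = 0.02) {
  pk <- find_peaks(pdist$energy, pdist$prob, prominence_frac)
  # end maxima also count as modes of P(E|T) (distribution support is finite)
  m <- nrow(pdist)
  if (m >= 2 && pdist$prob[1] > pdist$prob[2])
    pk <- rbind(data.frame(x = pdist$energy[1], y = pdist$prob[1]), pk)
  if (m >= 2 && pdist$prob[m] > pdist$prob[m - 1])
    pk <- rbind(pk, data.frame(x = pdist$energy[m], y = pdist$prob[m]))
  if (nrow(pk) < 2)
    return(list(is_bimodal = FALSE, peaks = pk$x))
  pk <- pk[order(pk$y, decreasing = TRUE)[1:2], ]
  pk <- pk[order(pk$x), ]
  between <- pdist$prob[pdist$energy > pk$x[1] & pdist$energy < pk$x[2]]
  if (!length(between)) return(list(is_bimodal = FALSE, peaks = pk$x))
  valley <- min(between)
  list(is_bimodal = valley <= depth_factor * min(pk$y), peaks = pk$x)
}

#' Locate a transition from several canonical observables
#'
#' Each observable curve (e.g. \eqn{C_N(T)}, \eqn{d\langle R_g^2\rangle/dT})
#' locates the transition at its main peak; the consensus transition
#' temperature is the mean of the per-observable main-peak positions and the
#' uncertainty interval is their min-max spread — the shift of the peak
#' between observables, not a statistical error, is what limits how well a
#' finite chain's pseudo transition temperature is defined.
#'
#' @param curves Named list; each element is a data frame with columns
#'   `T` and `value`.
#' @param prominence_frac Peak prominence threshold.
#' @return A one-row `transition_records` data frame (location, interval
#'   lower/upper, per-observable peaks as an attribute), or zero rows if no
#'   observable shows a peak.
#' @export
locate_transitions_canonical <- function(curves, prominence_frac = 0.05) {
  peaks <- vapply(curves, function(cv) {
    pk <- find_peaks(cv$T, cv$value, prominence_frac)
    if (!nrow(pk)) return(NA_real_)
    pk$x[which.max(pk$y)]          # main peak; ties toward lower T via order
  }, numeric(1))
  peaks <- peaks[!is.na(peaks)]
  if (!length(peaks)) {
    out <- data.frame(location = numeric(0), lower = numeric(0),
                      upper = numeric(0))
    class(out) <- c("transition_records", "data.frame")
    return(out)
  }
  out <- data.frame(location = mean(peaks), lower = min(peaks),
                    upper = max(peaks))
  class(out) <- c("transition_records", "data.frame")
  attr(out, "observable_peaks") <- peaks
  out
}

#' Canonical curve family over a temperature grid
#'
#' Convenience wrapper evaluating \eqn{\ln Z}, \eqn{\langle E \rangle},
#' \eqn{C_N}, \eqn{\langle R_g^2 \rangle} and its temperature derivative
#' (central differences on the grid) over a linear temperature grid.
#'
#' @param dos A [dos_estimate()].
#' @param obs Optional `energy_observables` for the \eqn{R_g^2} columns.
#' @param temps Temperature grid; default `seq(0.05, 2, by = 0.005)`
#'   (units \eqn{\epsilon/k_B}).
#' @return Data frame (T, lnZ, E_mean, Cv, and when `obs` is given
#'   rg2_mean, drg2_dT).
#' @export
canonical_curves <- function(dos, obs = NULL,
                             temps = seq(0.05, 2, by = 0.005)) {
  out <- data.frame(T = temps,
                    lnZ = log_partition_function(dos, temps),
                    E_mean = mean_energy(dos, temps),
                    Cv = specific_heat(dos, temps))
  if (!is.null(obs)) {
    rg2 <- canonical_average(obs, dos, temps, field = "rg2")
    n <- length(temps)
    d <- rep(NA_real_, n)
    d[2:(n - 1)] <- (rg2[3:n] - rg2[1:(n - 2)]) / (temps[3:n] - temps[1:(n - 2)])
    out$rg2_mean <- rg2
    out$drg2_dT <- d
  }
  out
}
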