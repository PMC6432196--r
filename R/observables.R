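#' Squared radius of gyration
#'
#' Mean squared distance of the monomers from their centroid, in units of
#' \eqn{\sigma^2}.  For a straight rod of N monomers at spacing L this is
#' \eqn{L^2 (N^2 - 1) / 12}, the maximum over all conformations at fixed N
#' and L.
#'
#' @param conf N x 3 coordinate matrix.
#' @return Non-negative scalar.
#' @export
radius_of_gyration_sq <- function(conf) {
  conf <- as_coord_matrix(conf)
  ctr <- colMeans(conf)
  mean(rowSums(sweep(conf, 2, ctr)^2))
}

#' Contact map of a conformation
#'
#' Binary symmetric N x N matrix with entry (i, j) = 1 iff |i - j| >= 2 and
#' the pair distance lies in the attraction well \eqn{[1, \lambda]}.  The
#' contact definition reuses the energy well, so the number of 1-entries in
#' the upper triangle times \eqn{-\epsilon} equals the conformation energy —
#' a standard protein-analysis tool here used to follow native-state (e.g.
#' trefoil) formation with temperature.
#'
#' @param conf N x 3 coordinate matrix.
#' @param well_width Well range \eqn{\lambda}.
#' @return Integer N x N matrix; diagonal and first off-diagonals are 0.
#' @export
contact_map <- function(conf, well_width) {
  conf <- as_coord_matrix(conf)
  cpp_contact_map(conf, well_width)
}

#' Create an empty per-energy observable accumulator
#'
#' Holds, for each integer energy level, the sample count and running
#' arithmetic means of \eqn{R_g^2} and of the contact matrix, updated with
#' the numerically stable incremental-mean rule.  These energy-resolved
#' means are the input of canonical reweighting.
#'
#' @param n Number of monomers.
#' @return An `obs_accumulator` environment.
#' @export
obs_accumulator <- function(n) {
  acc <- new.env(parent = emptyenv())
  acc$n <- as.integer(n)
  acc$count <- numeric(0)       # named by energy
  acc$rg2 <- numeric(0)
  acc$cmat <- list()
  class(acc) <- "obs_accumulator"
  acc
}

#' Accumulate one configuration into the per-energy means
#'
#' @param acc An [obs_accumulator()].
#' @param e Exact energy of `conf` (integer).  With `check = TRUE` the
#'   energy is recomputed and a mismatch is an error.
#' @param conf N x 3 coordinate matrix.
#' @param params [model_params()] (needed for the contact well and checks).
#' @param check Recompute the energy and verify it equals `e`.
#' @return `acc`, invisibly (updated in place).
#' @export
obs_accumulate <- function(acc, e, conf, params, check = FALSE) {
  stopifnot(inherits(acc, "obs_accumulator"))
  conf <- as_coord_matrix(conf)
  if (check) {
    e2 <- total_energy(conf, params)
    if (!identical(as.numeric(e), as.numeric(e2)))
      stop("internal consistency: stated energy ", e,
           " != recomputed energy ", e2)
  }
  key <- as.character(e)
  if (is.na(match(key, names(acc$count)))) {
    acc$count[key] <- 0
    acc$rg2[key] <- 0
    acc$cmat[[key]] <- matrix(0, acc$n, acc$n)
  }
  k <- acc$count[key] + 1
  acc$count[key] <- k
  acc$rg2[key] <- acc$rg2[key] + (radius_of_gyration_sq(conf) - acc$rg2[key]) / k
  cm <- contact_map(conf, params$well_width)
  acc$cmat[[key]] <- acc$cmat[[key]] + (cm - acc$cmat[[key]]) / k
  invisible(acc)
}

#' Tabulate an observable accumulator
#'
#' @param acc An [obs_accumulator()].
#' @return An `energy_observables` data frame (energy, count, rg2_mean) with
#'   the contact-frequency matrices in the `"contact_freq"` attribute, the
#'   same container [run_samc()] returns.
#' @export
obs_table <- function(acc) {
  e <- as.numeric(names(acc$count))
  o <- order(e)
  out <- data.frame(energy = e[o], count = unname(acc$count[o]),
                    rg2_mean = unname(acc$rg2[o]))
  class(out) <- c("energy_observables", "data.frame")
  attr(out, "contact_freq") <- stats::setNames(acc$cmat[o], e[o])
  attr(out, "n") <- acc$n
  out
}

#' Contact-frequency matrix at an energy level
#'
#' @param obs An `energy_observables` table (from [run_samc()] or
#'   [obs_table()]).
#' @param e Energy level.
#' @return N x N frequency matrix in \[0, 1\], or NULL if the level carries
#'   no samples.
#' @export
contact_freq <- function(obs, e) {
  cf <- attr(obs, "contact_freq")
  cf[[as.character(e)]]
}
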