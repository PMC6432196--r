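#' Brute-force uniform-sampling density of states (small chains)
#'
#' Independent ground truth for the SAMC engine: chains are grown by drawing
#' every bond direction uniformly on the unit sphere; hard-core violators
#' are discarded and the energies of the survivors histogrammed.  Because
#' the bond lengths are fixed, the configuration integral factorizes over
#' independent bond directions, so the surviving-sample energy frequencies
#' are proportional to g(E) restricted to self-avoiding states, and
#' differences of log frequencies estimate differences of \eqn{\ln g(E)}.
#' Standard errors are binomial.
#'
#' @param n Number of monomers; guarded to `n <= max_n` because the survivor
#'   fraction and level count explode with chain length.
#' @param bond_length Bond length L.
#' @param well_width Well range \eqn{\lambda}.
#' @param n_samples Number of chains drawn.
#' @param seed Integer RNG seed (`NULL`: continue the session stream).
#' @param max_n Cost guard, default 8.
#' @return An `oracle_dos` data frame (energy, count, freq, se) with
#'   attributes `n_valid`, `n_total`, `seed`; `freq` is relative to the
#'   surviving (self-avoiding) sample.
#' @examples
#' od <- uniform_dos(3, 1.0, 1.1, 1e5, seed = 7)
#' od$freq[od$energy == -1]  # ~ (1.1^2 - 1) / (4 - 1) = 0.07
#' @export
uniform_dos <- function(n, bond_length, well_width, n_samples, seed = NULL,
                        max_n = 8L) {
  if (n > max_n)
    stop("n = ", n, " exceeds the oracle cost guard (max_n = ", max_n, ")")
  if (n < 2) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- cpp_uniform_dos(as.integer(n), bond_length, well_width,
                         as.double(n_samples))
  if (res$n_valid == 0) stop("no self-avoiding chain survived the sampling")
  freq <- res$counts / res$n_valid
  out <- data.frame(energy = res$energies, count = res$counts, freq = freq,
                    se = sqrt(freq * (1 - freq) / res$n_valid))
  class(out) <- c("oracle_dos", "data.frame")
  attr(out, "n_valid") <- res$n_valid
  attr(out, "n_total") <- res$n_total
  attr(out, "seed") <- seed
  out
}

#' Exact contact probability of the 3-mer
#'
#' For a 3-monomer chain the squared end distance \eqn{r_{13}^2} of two
#' isotropic bonds is uniform on \eqn{[0, 4L^2]}, so the probability that a
#' surviving (self-avoiding, \eqn{r_{13} \ge 1}) conformation has its ends
#' inside the well is \eqn{(\lambda^2 - 1)/(4L^2 - 1)} when
#' \eqn{2L > \lambda}, and 1 when \eqn{2L \le \lambda} (permanent contact).
#' This closed form anchors both the oracle and the SAMC engine.
#'
#' @param bond_length Bond length L in (0.5, 1].
#' @param well_width Well range \eqn{\lambda} in (1, 2).
#' @return Probability that E = \eqn{-\epsilon} given self-avoidance.
#' @examples
#' n3_contact_fraction(1, 1.1)  # 0.21 / 3 = 0.07
#' @export
n3_contact_fraction <- function(bond_length, well_width) {
  if (bond_length <= 0.5 || bond_length > 1)
    stop("bond_length must lie in (0.5, 1]")
  if (well_width <= 1 || well_width >= 2)
    stop("well_width must lie in (1, 2)")
  if (2 * bond_length <= well_width) return(1)
  (well_width^2 - 1) / (4 * bond_length^2 - 1)
}

#' ln g differences from an oracle histogram
#'
#' Converts the survivor-frequency histogram into
#' \eqn{\ln g(E) - \ln g(E_{ref})} estimates with multinomial standard
#' errors \eqn{\sqrt{1/n_E + 1/n_{ref}}} (delta method, covariance
#' included).  Levels with fewer than `min_count` survivors are dropped:
#' below that the log-frequency is not approximately Gaussian and a
#' standard-error comparison is meaningless.
#'
#' @param od An `oracle_dos` from [uniform_dos()].
#' @param e_ref Reference energy level (default 0).
#' @param min_count Minimal survivor count per level, default 50.
#' @return Data frame (energy, dlng, dlng_se).
#' @export
oracle_lng_differences <- function(od, e_ref = 0, min_count = 50) {
  od <- od[od$count >= min_count, ]
  i <- match(e_ref, od$energy)
  if (is.na(i)) stop("reference level E = ", e_ref, " not in the oracle histogram")
  data.frame(energy = od$energy,
             dlng = log(od$count / od$count[i]),
             dlng_se = sqrt(1 / od$count + 1 / od$count[i]))
}

#' Pairwise ln g differences with replicate-based errors from SAMC
#'
#' Convenience used to compare engine and oracle: runs `k` independent SAMC
#' replicates (sub-seeded from `seed`) and returns, for each energy level,
#' the mean of \eqn{\ln g(E) - \ln g(E_{ref})} across replicates and its
#' standard error \eqn{sd/\sqrt{k}}, with the reference level `e_ref`.
#'
#' @param params [model_params()].
#' @param schedule [samc_schedule()].
#' @param n_steps Steps per replicate.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param k Number of replicates (>= 2).
#' @param e_ref Reference energy level (default 0).
#' @param ... Further arguments to [run_samc()].
#' @return Data frame (energy, dlng_mean, dlng_se) over levels visited in
#'   every replicate.
#' @export
samc_lng_differences <- function(params, schedule, n_steps, seed, k = 4L,
                                 e_ref = 0, ...) {
  if (k < 2) stop("need at least 2 replicates for an error estimate")
  reps <- lapply(seq_len(k), function(r) {
    run <- run_samc(params, schedule, n_steps, seed = seed + r, ...)
    d <- run$dos[run$dos$visits > 0, ]
    if (!e_ref %in% d$energy)
      stop("reference level E = ", e_ref, " not visited in replicate ", r)
    data.frame(energy = d$energy,
               dlng = d$ln_g - d$ln_g[d$energy == e_ref])
  })
  common <- Reduce(intersect, lapply(reps, function(d) d$energy))
  vals <- sapply(reps, function(d) d$dlng[match(common, d$energy)])
  data.frame(energy = common,
             dlng_mean = rowMeans(vals),
             dlng_se = apply(vals, 1, stats::sd) / sqrt(k))
}
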