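#' SAMC gain schedule
#'
#' Stochastic approximation gain \eqn{\gamma_t = \gamma_0 \min(1, t_0/t)}:
#' constant over an initial plateau of `t0` steps, then decaying like 1/t.
#' This satisfies both convergence conditions of stochastic approximation —
#' \eqn{\sum_t \gamma_t = \infty} (the 1/t tail diverges logarithmically) and
#' \eqn{\sum_t \gamma_t^\nu < \infty} for any \eqn{\nu \in (1, 2)}.
#'
#' @param gamma0 Initial modification factor (> 0); default 1.
#' @param t0 Plateau length in steps (> 0); default 1e6.
#' @return A `samc_schedule` object.
#' @export
samc_schedule <- function(gamma0 = 1.0, t0 = 1e6) {
  if (!is.finite(gamma0) || gamma0 <= 0) stop("gamma0 must be > 0")
  if (!is.finite(t0) || t0 <= 0) stop("t0 must be > 0")
  structure(list(gamma0 = gamma0, t0 = t0), class = "samc_schedule")
}

#' Gain factor at step t
#'
#' @param t Step index (>= 1), vectorized.
#' @param schedule A [samc_schedule()].
#' @return \eqn{\gamma_t}.
#' @export
gamma_schedule <- function(t, schedule) {
  if (any(t < 1)) stop("step index t must be >= 1")
  schedule$gamma0 * pmin(1, schedule$t0 / t)
}

#' Flat-histogram acceptance probability
#'
#' \eqn{A = \min(1, g(E_{old})/g(E_{new}))}, computed in log space: states
#' whose current density-of-states estimate is lower than the present one are
#' always accepted, which drives the random walk toward a flat energy
#' histogram.
#'
#' @param ln_g_old,ln_g_new Current log density-of-states estimates of the
#'   old and candidate energy levels (finite).
#' @return Acceptance probability in \[0, 1\].
#' @export
acceptance_probability <- function(ln_g_old, ln_g_new) {
  if (any(!is.finite(ln_g_old)) || any(!is.finite(ln_g_new)))
    stop("ln g values must be finite (forbidden states are rejected upstream)")
  pmin(1, exp(ln_g_old - ln_g_new))
}

#' One SAMC estimate update
#'
#' Adds \eqn{\gamma_t (\delta_{E,E'} - 1/M)} to every grid bin: the
#' post-decision energy bin gains \eqn{\gamma_t (1 - 1/M)} while all other
#' bins lose \eqn{\gamma_t / M}, so the sum of `ln_g` over the grid is
#' exactly conserved.  The visit count of the post-decision bin is
#' incremented.
#'
#' @param dos A [dos_estimate()].
#' @param e_accepted Post-decision energy (the retained current energy: the
#'   old one on rejection, the candidate on acceptance).  Must be on the
#'   grid.
#' @param gamma Gain \eqn{\gamma_t} for this step.
#' @return The updated `dos_estimate`.
#' @export
samc_update <- function(dos, e_accepted, gamma) {
  i <- match(e_accepted, dos$energy)
  if (is.na(i))
    stop("energy ", e_accepted, " is off the grid; extend the grid first")
  m <- nrow(dos)
  dos$ln_g <- dos$ln_g - gamma / m
  dos$ln_g[i] <- dos$ln_g[i] + gamma
  dos$visits[i] <- dos$visits[i] + 1L
  dos
}

#' Construct a density-of-states estimate
#'
#' Discrete estimate of \eqn{\ln g(E)} (the micro-canonical entropy
#' \eqn{S(E)}) on a strictly increasing integer energy grid, with the visit
#' histogram of the run that produced it.
#'
#' @param energy Strictly increasing integer energies (units of
#'   \eqn{\epsilon}).
#' @param ln_g Log density of states per level.
#' @param visits Non-negative visit counts per level.
#' @param meta Named list of run metadata (params, schedule, steps, seed).
#' @return A `dos_estimate` (data frame with attributes).
#' @export
dos_estimate <- function(energy, ln_g = numeric(length(energy)),
                         visits = numeric(length(energy)), meta = list()) {
  energy <- as.numeric(energy)
  if (any(energy != round(energy))) stop("energies must be integers")
  if (is.unsorted(energy, strictly = TRUE))
    stop("energies must be strictly increasing")
  if (any(visits < 0)) stop("visits must be >= 0")
  if (any(visits > 0 & !is.finite(ln_g)))
    stop("every visited level must have finite ln_g")
  out <- data.frame(energy = energy, ln_g = as.numeric(ln_g),
                    visits = as.numeric(visits))
  class(out) <- c("dos_estimate", "data.frame")
  attr(out, "meta") <- meta
  out
}

#' @export
print.dos_estimate <- function(x, ...) {
  cat(sprintf("density-of-states estimate: %d levels, E in [%d, %d], %s visits\n",
              nrow(x), min(x$energy), max(x$energy),
              format(sum(x$visits), big.mark = ",")))
  NextMethod()
}

#' Run a SAMC simulation
#'
#' Estimates \eqn{\ln g(E)} of the square-well chain by a flat-histogram
#' random walk: starting from the straight rod and \eqn{g_0(E) = 1},
#' configurations are proposed with symmetric bond-preserving moves,
#' hard-core violators are rejected outright, others are accepted with
#' probability \eqn{\min(1, g(E_{old})/g(E_{new}))}, and after every step
#' the estimate of the retained energy is raised by \eqn{\gamma_t (1 - 1/M)}
#' while all other bins drop by \eqn{\gamma_t / M}.  Energies are exact
#' integers (minus the contact count), so bins are integer labels; by
#' default the grid grows adaptively as new energies are discovered.
#'
#' Per-energy observables (squared radius of gyration and the contact
#' frequency matrix) are accumulated as arithmetic means over visited
#' configurations, by default only during the second half of the run where
#' the gain is small and the estimate nearly stationary.
#'
#' @param params A [model_params()].
#' @param schedule A [samc_schedule()].
#' @param n_steps Number of Monte Carlo steps (>= 1).
#' @param seed Integer RNG seed; the run is fully reproducible from it.
#'   `NULL` continues the session RNG stream (used for bit-exact resumes).
#' @param mset A [move_set()].
#' @param grid_policy `"adaptive"` (grid grows as energies are discovered;
#'   default) or `"fixed"` (declared `grid_range`; visiting an energy
#'   outside it is an error, never silent).
#' @param grid_range Integer `c(e_min, e_max)` for the fixed policy.
#' @param obs `"final_half"` (default: accumulate observables from step
#'   `n_steps/2`, avoiding early-phase bias from a moving g estimate) or
#'   `"all"`.
#' @param obs_stride Accumulate observables every `obs_stride`-th step
#'   (default 1: every visited configuration).
#' @param init A previous `samc_run` to continue from (same params); the
#'   schedule clock, grid, conformation and visit counts carry over, so
#'   splitting a run into checkpointed segments reproduces the unsplit run
#'   bit-exactly when `seed = NULL` on the continuation.
#' @return A `samc_run` list: `dos` ([dos_estimate()]), `observables`
#'   (per-energy counts, mean Rg^2, contact frequency matrices),
#'   `ground_state` (lowest-energy conformation seen and its energy),
#'   `acceptance_rate`, `final_conf`, and the effective configuration.
#' @examples
#' \donttest{
#' p <- model_params(3, 1.0)
#' run <- run_samc(p, samc_schedule(1, 1e4), n_steps = 2e5, seed = 1)
#' run$dos
#' }
#' @export
run_samc <- function(params, schedule = samc_schedule(), n_steps,
                     seed = NULL, mset = move_set(),
                     grid_policy = c("adaptive", "fixed"), grid_range = NULL,
                     obs = c("final_half", "all"), obs_stride = 1L,
                     init = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(schedule, "samc_schedule"))
  grid_policy <- match.arg(grid_policy)
  obs <- match.arg(obs)
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (grid_policy == "fixed") {
    if (is.null(grid_range) || length(grid_range) != 2L)
      stop("fixed grid policy needs grid_range = c(e_min, e_max)")
  } else {
    grid_range <- c(0L, 0L)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (is.null(init)) {
    conf0 <- straight_rod(params)
    t_offset <- 0
    init_e <- integer(0); init_lg <- numeric(0); init_v <- numeric(0)
    init_base <- 0
  } else {
    stopifnot(inherits(init, "samc_run"))
    conf0 <- init$final_conf
    t_offset <- init$config$total_steps
    init_e <- as.integer(init$dos$energy)
    init_lg <- if (!is.null(init$dos$ln_g_final)) init$dos$ln_g_final else
      init$dos$ln_g
    init_v <- init$dos$visits
    init_base <- attr(init$dos, "base")
    if (is.null(init_base)) init_base <- 0
  }

  res <- cpp_run_samc(as_coord_matrix(conf0), params$well_width,
                      as.double(n_steps), schedule$gamma0, schedule$t0,
                      mset$weights, mset$max_angles,
                      grid_policy, as.integer(grid_range),
                      obs_from = if (obs == "all") 1 else floor(n_steps / 2) + 1,
                      obs_stride = as.integer(obs_stride),
                      t_offset = t_offset,
                      avg_from = floor(n_steps / 2) + 1,
                      init_energies = init_e, init_ln_g = init_lg,
                      init_visits = init_v, init_base = init_base)

  # ln_g is the Polyak-averaged late-phase estimate (much lower variance
  # than the final iterate, which is kept alongside for diagnostics and for
  # bit-exact checkpoint resumes).
  dos <- dos_estimate(res$energies, res$ln_g_avg, res$visits,
                      meta = list(params = params, schedule = schedule,
                                  n_steps = n_steps, seed = seed,
                                  grid_policy = grid_policy))
  dos$ln_g_final <- res$ln_g
  attr(dos, "base") <- res$base
  obs_tab <- data.frame(energy = res$energies, count = res$obs_count,
                        rg2_mean = res$rg2_mean)
  class(obs_tab) <- c("energy_observables", "data.frame")
  attr(obs_tab, "contact_freq") <-
    stats::setNames(res$contact_freq, res$energies)
  attr(obs_tab, "n") <- params$n
  ground <- list(energy = res$ground_energy, conf = res$ground_conf)
  if (!is.null(init) && init$ground_state$energy < ground$energy)
    ground <- init$ground_state
  structure(list(
    dos = dos,
    observables = obs_tab,
    ground_state = ground,
    acceptance_rate = res$acceptance_rate,
    final_conf = res$final_conf,
    config = list(params = params, schedule = schedule,
                  n_steps = n_steps, seed = seed, grid_policy = grid_policy,
                  move_set = mset, obs = obs, obs_stride = obs_stride,
                  total_steps = t_offset + n_steps)),
    class = "samc_run")
}

#' @export
print.samc_run <- function(x, ...) {
  cat(sprintf(
    "SAMC run: N = %d, L = %g, lambda = %g | %s steps | %d levels | acc %.1f%%\n",
    x$config$params$n, x$config$params$bond_length,
    x$config$params$well_width,
    format(x$config$n_steps, big.mark = ","), nrow(x$dos),
    100 * x$acceptance_rate))
  cat(sprintf("lowest energy visited: %g\n", x$ground_state$energy))
  invisible(x)
}
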