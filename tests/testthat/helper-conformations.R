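# Shared fixture builders: deterministic geometric conformations and random
# valid chains, all generated in code.

# planar chain with prescribed internal bond angles (radians), in the xy plane
planar_chain <- function(bond_length, angles) {
  n <- length(angles) + 2L
  conf <- matrix(0, n, 3)
  dir <- 0
  for (i in 2:n) {
    if (i > 2) dir <- dir + (pi - angles[i - 2L])
    conf[i, ] <- conf[i - 1L, ] + bond_length * c(cos(dir), sin(dir), 0)
  }
  conf
}

# random self-avoiding conformation grown with per-bond retries (small n
# only; sampling bias is irrelevant for the invariant checks it serves)
random_valid_chain <- function(params, max_tries = 200) {
  conf <- matrix(0, params$n, 3)
  i <- 2L
  tries <- 0L
  while (i <= params$n) {
    u <- stats::rnorm(3)
    conf[i, ] <- conf[i - 1, ] + params$bond_length * u / sqrt(sum(u^2))
    ok <- TRUE
    if (i > 2) {
      d2 <- rowSums((conf[seq_len(i - 2), , drop = FALSE] -
                       matrix(conf[i, ], i - 2, 3, byrow = TRUE))^2)
      ok <- all(d2 >= 1)
    }
    if (ok) {
      i <- i + 1L
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries) {          # back up one monomer and retry
        i <- max(2L, i - 1L)
        tries <- 0L
      }
    }
  }
  conf
}

random_rotation_matrix <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

# synthetic two-Gaussian density of states with a linear tilt:
# ln g = ln(exp(-(E-a)^2/(2 s^2)) + exp(-(E-b)^2/(2 s^2))) + E/t_match.
# Has a convex intruder between the humps (gamma peak > 0) and P(E|T) is
# symmetric-bimodal at exactly T = t_match (the tilt cancels there).
two_gaussian_dos <- function(a = -40, b = -10, s = 4, t_match = 1,
                             emin = -60, emax = 0) {
  e <- emin:emax
  lg <- log(exp(-(e - a)^2 / (2 * s^2)) + exp(-(e - b)^2 / (2 * s^2))) +
    e / t_match
  dos_estimate(e, lg, visits = rep(1, length(e)))
}

# strictly concave entropy with a localized dip that makes gamma(E) = S''(E)
# peak locally while staying below zero (second-order signature)
concave_bump_dos <- function(emin = -60, emax = 0, e0 = -30, amp = 0.05, w = 3) {
  e <- emin:emax
  lg <- -0.005 * (e - emax)^2 + 0.8 * (e - emin) -
    amp * exp(-(e - e0)^2 / (2 * w^2))
  dos_estimate(e, lg, visits = rep(1, length(e)))
}
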