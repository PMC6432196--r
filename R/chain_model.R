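#' Model parameters for a fused-hard-sphere square-well chain
#'
#' Defines the coarse-grained chain Hamiltonian: `n` hard spheres of diameter
#' \eqn{\sigma = 1} joined by bonds of fixed length `bond_length` (in units of
#' \eqn{\sigma}), with a square-well attraction of range `well_width` and
#' depth `well_depth` acting between all non-bonded monomer pairs.  Because
#' the spheres overlap for `bond_length < 1`, short bonds sterically restrict
#' the bond angle: the chain stiffness is set entirely by `bond_length`.
#'
#' Temperatures are measured in units of `well_depth / kB`.
#'
#' @param n Number of monomers (integer, at least 2).
#' @param bond_length Bond length L in (0.5, 1].  L = 0.5 is the rigid-rod
#'   limit where the only allowed bond angle is \eqn{\pi}; simulation
#'   requires L > 0.5.
#' @param well_width Square-well range \eqn{\lambda} (> 1); default 1.1.
#' @param well_depth Well depth \eqn{\epsilon} (> 0); the unit of energy,
#'   default 1.
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(20, 0.53)
#' classify_regime(p)
#' @export
model_params <- function(n, bond_length, well_width = 1.1, well_depth = 1) {
  stopifnot(length(n) == 1L, length(bond_length) == 1L, length(well_width) == 1L)
  n <- as.integer(n)
  if (is.na(n) || n < 2L)
    stop("n must be an integer >= 2")
  if (!is.finite(bond_length) || bond_length <= 0.5 || bond_length > 1)
    stop("bond_length must lie in (0.5, 1]: L = 0.5 is the rigid-rod limit")
  if (!is.finite(well_width) || well_width <= 1)
    stop("well_width must be > 1")
  if (!is.finite(well_depth) || well_depth <= 0)
    stop("well_depth must be > 0")
  structure(
    list(n = n, bond_length = bond_length, well_width = well_width,
         well_depth = well_depth),
    class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("square-well chain: N = %d, L = %g, lambda = %g, eps = %g (%s)\n",
              x$n, x$bond_length, x$well_width, x$well_depth,
              classify_regime(x)))
  invisible(x)
}

#' Smallest sterically allowed bond angle
#'
#' For bond length L the hard cores of monomers i-1 and i+1 forbid internal
#' bond angles below \eqn{\vartheta_{min} = 2 \arcsin(1/(2L))}: at that angle
#' the next-nearest-neighbour distance \eqn{2 L \sin(\vartheta/2)} equals the
#' sphere diameter 1.  At L = 0.5 the only allowed angle is \eqn{\pi} (rigid
#' rod); the restriction vanishes entirely only for L >= 1.
#'
#' @param bond_length Bond length L with 0.5 <= L <= 1.
#' @return Minimal internal bond angle in radians.
#' @examples
#' min_bond_angle(0.5)   # pi: rigid rod
#' min_bond_angle(1.0)   # pi/3: tangent spheres
#' @export
min_bond_angle <- function(bond_length) {
  if (any(!is.finite(bond_length)) || any(bond_length < 0.5))
    stop("no valid conformation exists for bond_length < 0.5 ",
         "(next-nearest neighbours cannot avoid overlap)")
  if (any(bond_length > 1))
    stop("bond_length must be <= 1")
  2 * asin(1 / (2 * bond_length))
}

#' Stiffness regime of a parameter set
#'
#' Chains are `"stiff"` when the next-nearest-neighbour distance, which lies
#' in \eqn{[1, 2L]}, is bounded by the well range in every conformation
#' (\eqn{2L \le \lambda}): those pairs then interact permanently and
#' contribute a constant \eqn{-(N-2)\epsilon} to the energy.  `"flexible"`
#' is the tangent-sphere limit L = 1; everything between is
#' `"semi-flexible"`.
#'
#' @param params A `model_params` object, or a bond length L (in which case
#'   `well_width` must be given).
#' @param well_width Square-well range, used when `params` is a bare L.
#' @return One of `"stiff"`, `"semi-flexible"`, `"flexible"`.
#' @export
classify_regime <- function(params, well_width = NULL) {
  if (inherits(params, "model_params")) {
    L <- params$bond_length
    lam <- params$well_width
  } else {
    L <- params
    if (is.null(well_width)) stop("well_width required when params is a bond length")
    lam <- well_width
  }
  if (L <= 0.5 || L > 1 || lam <= 1) stop("invalid (bond_length, well_width)")
  if (2 * L <= lam) "stiff" else if (L == 1) "flexible" else "semi-flexible"
}

#' Square-well pair potential
#'
#' \eqn{U(r) = \infty} for r < 1 (hard core), \eqn{-\epsilon} for
#' \eqn{1 \le r \le \lambda}, and 0 beyond the well.  The boundaries r = 1
#' and r = \eqn{\lambda} (measure zero) are taken as in-well, so the straight
#' rod at \eqn{2L = \lambda} is a valid bound state.
#'
#' @param r Pair distance(s), >= 0.
#' @param well_width Well range \eqn{\lambda}.
#' @param well_depth Well depth \eqn{\epsilon}, default 1.
#' @return Numeric vector: `Inf` (hard-core violation), `-well_depth`, or 0.
#' @export
pair_potential <- function(r, well_width, well_depth = 1) {
  if (any(!is.finite(r)) || any(r < 0)) stop("pair distance must be >= 0")
  ifelse(r < 1, Inf, ifelse(r <= well_width, -well_depth, 0))
}

#' Straight-rod conformation
#'
#' All monomers collinear along the x axis with spacing `bond_length`.  This
#' is a valid (self-avoiding) conformation for every L >= 0.5 and is the
#' deterministic initial state of the sampler.  In the stiff regime its
#' energy is \eqn{-(N-2)\epsilon}: only the N-2 next-nearest pairs, at
#' distance 2L, sit inside the well.
#'
#' @param params A `model_params` object.
#' @return An N x 3 coordinate matrix.
#' @export
straight_rod <- function(params) {
  stopifnot(inherits(params, "model_params"))
  cbind(x = (seq_len(params$n) - 1) * params$bond_length, y = 0, z = 0)
}

as_coord_matrix <- function(conf) {
  conf <- as.matrix(conf)
  if (ncol(conf) != 3L || nrow(conf) < 1L || !is.numeric(conf))
    stop("a conformation is an N x 3 numeric coordinate matrix")
  storage.mode(conf) <- "double"
  conf
}

#' Validate a chain conformation against its parameters
#'
#' Checks the two defining invariants: all consecutive distances equal the
#' bond length (absolute tolerance `tol`), and all non-bonded pairs
#' (|i - j| >= 2) respect the hard core r >= 1.  Bonded pairs are exempt
#' from the core: the spheres are fused.
#'
#' @param conf N x 3 coordinate matrix.
#' @param params A `model_params` object.
#' @param tol Absolute tolerance on bond lengths, default 1e-9.
#' @return `conf`, invisibly; errors describe the violated invariant.
#' @export
validate_conformation <- function(conf, params, tol = 1e-9) {
  conf <- as_coord_matrix(conf)
  if (nrow(conf) != params$n)
    stop("conformation has ", nrow(conf), " monomers, params expect ", params$n)
  bl <- sqrt(rowSums((conf[-1, , drop = FALSE] - conf[-nrow(conf), , drop = FALSE])^2))
  bad <- which(abs(bl - params$bond_length) > tol)
  if (length(bad))
    stop("bond length violated at bond ", bad[1], ": |r| = ", bl[bad[1]])
  if (!is_self_avoiding(conf))
    stop("hard-core violation: some non-bonded pair closer than 1")
  invisible(conf)
}

#' Total square-well energy of a conformation
#'
#' Sums the pair potential over all non-bonded pairs (|i - j| >= 2); bonded
#' pairs are excluded entirely (fused spheres).  The result is always an
#' integer multiple of `-well_depth`, i.e. minus the number of non-bonded
#' contacts, or `Inf` for a forbidden (hard-core overlapping) conformation —
#' never a finite non-integer.
#'
#' @param conf N x 3 coordinate matrix.
#' @param params A `model_params` object.
#' @return Energy in units of \eqn{\epsilon}; `Inf` if forbidden.
#' @examples
#' p <- model_params(20, 0.53)
#' total_energy(straight_rod(p), p)  # -18
#' @export
total_energy <- function(conf, params) {
  conf <- as_coord_matrix(conf)
  if (nrow(conf) != params$n)
    stop("conformation has ", nrow(conf), " monomers, params expect ", params$n)
  ct <- cpp_contact_count(conf, params$well_width)
  if (ct < 0L) Inf else -as.numeric(ct) * params$well_depth
}

#' Self-avoidance predicate
#'
#' TRUE iff every pair with |i - j| >= 2 has distance >= 1 (the hard core of
#' the square-well potential).  Bonded pairs are exempt.
#'
#' @param conf N x 3 coordinate matrix.
#' @return Logical scalar.
#' @export
is_self_avoiding <- function(conf) {
  conf <- as_coord_matrix(conf)
  cpp_contact_count(conf, 1.0) >= 0L
}
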