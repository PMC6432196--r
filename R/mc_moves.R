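#' Monte Carlo move set
#'
#' The sampler explores configuration space with three bond-length-preserving
#' rigid-rotation moves: pivot (rotate one chain end about an arbitrary axis
#' through a pivot monomer), crankshaft (rotate an interior monomer about the
#' axis through its two neighbours), and end rotation (rotate a terminal
#' monomer about its bonded neighbour).  Rotation angles are drawn uniformly
#' in `[-max_angle, +max_angle]`, axes isotropically, so the proposal density
#' is symmetric and the flat-histogram acceptance rule applies unmodified.
#'
#' @param weights Named or positional non-negative selection weights for
#'   `pivot`, `crankshaft`, `end`; must not all be zero.
#' @param max_angles Maximum rotation angle per kind (radians), recycled to
#'   length 3; default `pi` (global moves).
#' @return A `move_set` object.
#' @export
move_set <- function(weights = c(pivot = 1, crankshaft = 1, end = 1),
                     max_angles = pi) {
  weights <- rep_len(as.numeric(weights), 3L)
  max_angles <- rep_len(as.numeric(max_angles), 3L)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("move weights must be non-negative with positive sum")
  if (any(max_angles < 0)) stop("max_angles must be >= 0")
  structure(list(weights = weights, max_angles = max_angles),
            class = "move_set")
}

#' Pivot move
#'
#' Rigidly rotates all monomers after `pivot` about the axis `axis` anchored
#' at the pivot monomer; monomers up to and including the pivot are
#' untouched.  Bond lengths are preserved exactly (rigid rotation); validity
#' (hard core) and energy are the caller's concern.
#'
#' @param conf N x 3 coordinate matrix.
#' @param pivot Pivot monomer index in 1..N.
#' @param axis Rotation axis (3-vector, need not be normalized).
#' @param angle Rotation angle in radians.
#' @return The moved N x 3 coordinate matrix.
#' @export
pivot_move <- function(conf, pivot, axis, angle) {
  conf <- as_coord_matrix(conf)
  n <- nrow(conf)
  if (pivot < 1 || pivot > n) stop("pivot index out of range")
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("degenerate rotation axis")
  out <- cpp_rotate_tail(conf, as.integer(pivot) - 1L, axis / nrm, angle)
  dimnames(out) <- dimnames(conf)
  out
}

#' Crankshaft move
#'
#' Rotates interior monomer `i` about the axis through monomers i-1 and i+1;
#' every other monomer is untouched and the two adjacent bond lengths are
#' preserved.  When the chain folds exactly back (monomers i-1 and i+1
#' coincide) the axis is degenerate and the move falls back to rotating
#' monomer i on its sphere of radius L about monomer i-1, about a random
#' axis.
#'
#' @param conf N x 3 coordinate matrix.
#' @param i Interior monomer index, 2..N-1.
#' @param angle Rotation angle in radians.
#' @return The moved N x 3 coordinate matrix.
#' @export
crankshaft_move <- function(conf, i, angle) {
  conf <- as_coord_matrix(conf)
  n <- nrow(conf)
  if (i < 2 || i > n - 1) stop("crankshaft index must be interior (2..N-1)")
  ax <- conf[i + 1, ] - conf[i - 1, ]
  nrm <- sqrt(sum(ax^2))
  if (nrm < 1e-12) {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
  } else {
    ax <- ax / nrm
  }
  out <- conf
  out[i, ] <- rotate_point(conf[i, ], conf[i - 1, ], ax, angle)
  out
}

rotate_point <- function(p, origin, u, angle) {
  v <- p - origin
  c1 <- cos(angle); s1 <- sin(angle)
  origin + v * c1 + cross3(u, v) * s1 + u * sum(u * v) * (1 - c1)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Propose one Monte Carlo move
#'
#' Draws a move kind according to the set's weights, a uniform angle in
#' `[-max_angle, max_angle]` and an isotropic axis, and returns the candidate
#' conformation together with the move label.  Uses R's RNG, so sequences are
#' reproducible under [set.seed()].
#'
#' @param conf N x 3 coordinate matrix.
#' @param mset A [move_set()].
#' @return List with elements `conf` (candidate) and `move` (label).
#' @export
propose_move <- function(conf, mset = move_set()) {
  conf <- as_coord_matrix(conf)
  n <- nrow(conf)
  kind <- sample.int(3L, 1L, prob = mset$weights)
  label <- c("pivot", "crankshaft", "end")[kind]
  ang <- stats::runif(1, -mset$max_angles[kind], mset$max_angles[kind])
  if (kind == 1L) {
    piv <- sample.int(n - 1L, 1L)
    axis <- stats::rnorm(3)
    cand <- pivot_move(conf, piv, axis, ang)
  } else if (kind == 2L && n >= 3L) {
    i <- if (n == 3L) 2L else sample(2:(n - 1L), 1L)
    cand <- crankshaft_move(conf, i, ang)
  } else {
    e <- if (stats::runif(1) < 0.5) n else 1L
    nb <- if (e == n) n - 1L else 2L
    axis <- stats::rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    cand <- conf
    cand[e, ] <- rotate_point(conf[e, ], conf[nb, ], axis, ang)
    label <- "end"
  }
  list(conf = cand, move = label)
}
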