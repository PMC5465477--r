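# Geometry primitives shared by all analysis stages: minimum-image
# displacement and distance, rigid rotations, angles.

#' Minimum-image pairwise distances between two coordinate sets
#'
#' Computes the full pairwise distance matrix between rows of `a` and rows of
#' `b` under the orthorhombic minimum-image convention. Pass `box = NULL` to
#' compute plain Euclidean distances.
#'
#' @param a,b numeric matrices (n x 3, m x 3) in angstrom.
#' @param box length-3 box vector in angstrom, or `NULL` for no periodicity.
#' @return n x m matrix of distances in angstrom.
#' @export
pair_distances <- function(a, b, box = NULL) {
  a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) {
      if (box[k] <= 0) stop("box components must be > 0")
      dk <- dk - box[k] * round(dk / box[k])
    }
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Minimum distance between two atom sets
#'
#' @inheritParams pair_distances
#' @return smallest pairwise distance (angstrom).
#' @export
min_distance <- function(a, b, box = NULL) {
  if (NROW(a) == 0 || NROW(b) == 0) stop("atom sets must be non-empty")
  min(pair_distances(a, b, box))
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` degrees about unit `axis`.
#'
#' @param axis length-3 vector (normalized internally).
#' @param angle angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

#' Rotate coordinates about a pivot point
#' @param xyz n x 3 matrix.
#' @param axis rotation axis.
#' @param angle degrees.
#' @param pivot length-3 point the axis passes through.
#' @return rotated n x 3 matrix.
#' @export
rotate_about <- function(xyz, axis, angle, pivot = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle)
  sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, "+")
}

#' Angle between two vectors in degrees
#' @param v,w length-3 vectors.
#' @return angle in `[0, 180]` degrees.
#' @export
vector_angle <- function(v, w) {
  cosang <- sum(v * w) / sqrt(sum(v^2) * sum(w^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

## mass-weighted centre of mass of selected atoms
.com <- function(xyz, mass) {
  colSums(xyz * mass) / sum(mass)
}
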