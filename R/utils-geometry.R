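# Small 3D geometry toolkit shared by the scoring, surface and synthesis code.
# Conventions: coordinates are N x 3 matrices in Angstrom; quaternions are
# length-4 numeric vectors c(w, x, y, z) normalised to unit length.

#' Normalise a quaternion to unit length
#' @param q numeric length-4, (w, x, y, z)
#' @return unit quaternion
#' @keywords internal
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("degenerate quaternion")
  q / n
}

#' Quaternion to 3x3 rotation matrix
#' @param q unit quaternion (w, x, y, z)
#' @return 3x3 rotation matrix
#' @keywords internal
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Hamilton product of two quaternions
#' @keywords internal
quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' Axis-angle to quaternion
#' @param axis length-3 vector (need not be unit)
#' @param angle radians
#' @keywords internal
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) return(c(1, 0, 0, 0))
  axis <- axis / n
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Uniform random unit quaternion (Shoemake's method)
#' @keywords internal
quat_random <- function() {
  u <- stats::runif(3)
  c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )[c(2, 1, 3, 4)] # reorder so w is first; distribution is symmetric
}

#' Rotation matrix mapping unit vector a onto unit vector b
#' @keywords internal
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  cosab <- sum(a * b)
  if (cosab < -1 + 1e-12) {
    # opposite vectors: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(a[2] * p[3] - a[3] * p[2], a[3] * p[1] - a[1] * p[3], a[1] * p[2] - a[2] * p[1])
    return(quat_to_matrix(quat_from_axis_angle(ax, pi)))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cosab)
}

#' Pairwise squared distances between two coordinate sets
#' @param a n x 3 matrix
#' @param b m x 3 matrix
#' @return n x m matrix of squared distances
#' @keywords internal
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Place an atom by internal coordinates (NeRF construction)
#'
#' Given three previously placed atoms a-b-c, returns the position of atom d
#' with bond length |c-d| = length, angle b-c-d = angle and dihedral
#' a-b-c-d = torsion.
#' @param a,b,c length-3 position vectors
#' @param length bond length, Angstrom
#' @param angle bond angle in degrees
#' @param torsion dihedral in degrees
#' @keywords internal
place_atom <- function(a, b, c, length, angle, torsion) {
  angle <- angle * pi / 180
  torsion <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3], ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3], n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(
    -length * cos(angle),
    length * sin(angle) * cos(torsion),
    length * sin(angle) * sin(torsion)
  )
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Deterministic quasi-uniform points on the unit sphere (golden spiral)
#' @param n number of points
#' @return n x 3 matrix of unit vectors
#' @keywords internal
golden_spiral <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
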