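#' Euclidean distance between two points
#'
#' @param p,q Numeric 3-vectors (Angstrom).
#' @return Distance in Angstrom.
#' @export
vec_distance <- function(p, q) {
  sqrt(sum((p - q)^2))
}

#' Angle between two vectors
#'
#' The cosine is clamped to \code{[-1, 1]} before \code{acos} so that
#' round-off on (anti)parallel vectors can never produce \code{NaN}.
#'
#' @param u,v Numeric 3-vectors; both must have non-zero length.
#' @return Angle in degrees, in \code{[0, 180]}.
#' @export
vec_angle <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("vec_angle(): degenerate geometry, zero-length vector")
  }
  ct <- sum(u * v) / (nu * nv)
  ct <- max(-1, min(1, ct))
  acos(ct) * 180 / pi
}

#' Signed torsion angle about the b--c axis
#'
#' IUPAC convention: cis = 0, trans = 180, sign from the right-hand rule
#' looking along b to c. Reversing the atom order preserves the signed
#' value (\code{vec_dihedral(a,b,c,d) == vec_dihedral(d,c,b,a)}); mirror
#' reflection negates it.
#'
#' @param a,b,c,d Numeric 3-vectors defining the torsion a-b-c-d.
#' @return Dihedral angle in degrees, in \code{(-180, 180]}.
#' @export
vec_dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop("vec_dihedral(): degenerate geometry, collinear points")
  }
  m1 <- pracma_cross(b2 / sqrt(sum(b2^2)), n1)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# cross product; named to make clear it is the standard 3-vector cross
pracma_cross <- function(u, v) {
  c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
}

#' Ring centroid and best-fit plane normal
#'
#' The centroid is the arithmetic mean of the member coordinates; the normal
#' is the unit eigenvector of the smallest eigenvalue of the centered
#' covariance matrix (best-fit plane). The sign of the normal depends on the
#' construction order and is arbitrary: all consumers fold angles so that
#' theta and 180 - theta are equivalent.
#'
#' @param coords Numeric matrix, one row per ring member, columns x/y/z.
#' @param member_indices Optional atom indices recorded in the descriptor.
#' @return A list of class \code{ring_descriptor} with elements
#'   \code{centroid}, \code{normal} (unit vector) and
#'   \code{member_atom_indices}.
#' @export
ring_descriptor <- function(coords, member_indices = integer(0)) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) {
    stop("ring_descriptor(): at least 3 points are required")
  }
  centroid <- colMeans(coords)
  centered <- sweep(coords, 2, centroid)
  cv <- crossprod(centered) / nrow(coords)
  eig <- eigen(cv, symmetric = TRUE)
  # collinear points: two (near) zero eigenvalues -> plane undefined
  if (eig$values[2] < 1e-12 * max(eig$values[1], 1e-12)) {
    stop("ring_descriptor(): degenerate geometry, collinear points")
  }
  normal <- eig$vectors[, 3]
  normal <- normal / sqrt(sum(normal^2))
  structure(
    list(
      centroid = as.numeric(centroid),
      normal = as.numeric(normal),
      member_atom_indices = member_indices
    ),
    class = "ring_descriptor"
  )
}
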