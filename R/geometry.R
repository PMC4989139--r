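# Periodic-boundary geometry primitives. Coordinates in nm, angles in degrees.
# Boxes are orthorhombic (Lx, Ly, Lz); the minimum-image convention is applied
# per Cartesian component, which is exact for orthorhombic cells.

#' Minimum-image displacement
#'
#' Component-wise minimum-image displacement `b - a` under an orthorhombic box.
#'
#' @param a,b numeric vectors of length 3, or n x 3 matrices.
#' @param box numeric(3) box lengths in nm.
#' @return displacement(s) with each component folded into (-L/2, L/2].
#' @export
pbc_displacement <- function(a, b, box) {
  d <- b - a
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  } else {
    d <- d - box * round(d / box)
  }
  d
}

#' Minimum-image distance between two points
#' @inheritParams pbc_displacement
#' @return distance in nm.
#' @export
pbc_dist <- function(a, b, box) {
  d <- pbc_displacement(a, b, box)
  sqrt(sum(d * d))
}

#' All-pairs minimum-image distance matrix
#'
#' @param A,B coordinate matrices (nA x 3, nB x 3).
#' @param box numeric(3) box lengths.
#' @return nA x nB matrix of distances in nm.
#' @export
pbc_dist_matrix <- function(A, B, box) {
  dx <- outer(A[, 1], B[, 1], "-"); dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(A[, 2], B[, 2], "-"); dy <- dy - box[2] * round(dy / box[2])
  dz <- outer(A[, 3], B[, 3], "-"); dz <- dz - box[3] * round(dz / box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Minimum inter-set distance under periodic boundaries
#' @inheritParams pbc_dist_matrix
#' @export
pbc_min_dist <- function(A, B, box) min(pbc_dist_matrix(A, B, box))

#' Wrap coordinates into the primary box [0, L)
#' @param X n x 3 coordinate matrix.
#' @param box numeric(3).
#' @export
wrap_coords <- function(X, box) {
  for (k in 1:3) X[, k] <- X[, k] %% box[k]
  X
}

#' Rotate points about the z axis
#' @param X n x 3 (or n x 2) matrix.
#' @param angle_deg rotation angle, counter-clockwise viewed from +z.
#' @export
rotate_z <- function(X, angle_deg) {
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  Y <- X
  Y[, 1] <- ca * X[, 1] - sa * X[, 2]
  Y[, 2] <- sa * X[, 1] + ca * X[, 2]
  Y
}

#' Signed four-point dihedral angle
#'
#' Standard IUPAC convention: for points p1-p2-p3-p4 with bond vectors
#' b1 = p2-p1, b2 = p3-p2, b3 = p4-p3, the dihedral is
#' atan2((n1 x n2) . b2hat, n1 . n2) with n1 = b1 x b2, n2 = b2 x b3.
#' Right-handed, mapped to (-180, 180]. Each bond vector is min-imaged when a
#' box is supplied, so the computation is valid on wrapped coordinates as long
#' as no bond exceeds half a box length.
#'
#' @param p1,p2,p3,p4 numeric(3) positions in nm.
#' @param box optional numeric(3); when given, displacements are min-imaged.
#' @return angle in degrees in (-180, 180], or NA if any plane is degenerate
#'   (collinear defining points).
#' @export
dihedral_angle <- function(p1, p2, p3, p4, box = NULL) {
  if (is.null(box)) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  } else {
    b1 <- pbc_displacement(p1, p2, box)
    b2 <- pbc_displacement(p2, p3, box)
    b3 <- pbc_displacement(p3, p4, box)
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) return(NA_real_)
  b2hat <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * b2hat), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Wrap degrees into (-180, 180].
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# Smallest absolute circular difference between two angles in degrees.
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
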