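# Vector geometry primitives used throughout sampling and validation.
# All coordinates are Cartesian angstroms in a right-handed frame; all angles
# are degrees, with torsions reported in (-180, 180].

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))

.vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.vunit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

#' Signed torsion angle of four points
#'
#' Standard signed dihedral a-b-c-d: the angle between the plane (a, b, c) and
#' the plane (b, c, d), measured looking down the b->c axis, positive
#' clockwise (IUPAC convention).
#'
#' @param a,b,c,d numeric 3-vectors (angstroms).
#' @return Angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  if (.vnorm(n1) < 1e-9 || .vnorm(n2) < 1e-9)
    stop("degenerate geometry: three collinear points in dihedral")
  m1 <- .vcross(n1, .vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- .rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Bond angle of three points
#'
#' @param a,b,c numeric 3-vectors; the angle is at `b`.
#' @return Angle in degrees, in [0, 180].
#' @export
bond_angle <- function(a, b, c) {
  u <- .vunit(a - b)
  v <- .vunit(c - b)
  .rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Rodrigues rotation of points (n x 3 matrix) about the axis through `origin`
# with unit direction `axis`, by `angle` degrees (right-handed).
.rotate_about_axis <- function(xyz, origin, axis, angle) {
  u <- .vunit(axis)
  th <- .deg2rad(angle)
  ct <- cos(th); st <- sin(th)
  p <- sweep(xyz, 2L, origin)
  # R p = p cos + (u x p) sin + u (u.p)(1 - cos)
  ux <- p[, 2L] * u[3L] - p[, 3L] * u[2L]
  uy <- p[, 3L] * u[1L] - p[, 1L] * u[3L]
  uz <- p[, 1L] * u[2L] - p[, 2L] * u[1L]
  dp <- p %*% u
  out <- p * ct + cbind(ux, uy, uz) * st +
    outer(as.vector(dp) * (1 - ct), u)
  sweep(out, 2L, origin, `+`)
}

# Place atom D bonded to c, with bond length r, angle b-c-D = theta (deg) and
# torsion a-b-c-D = chi (deg). Standard internal-coordinate (NeRF) placement.
.place_atom <- function(a, b, c, r, theta, chi) {
  th <- .deg2rad(180 - theta)
  ph <- .deg2rad(chi)
  bc <- .vunit(c - b)
  n <- .vunit(.vcross(b - a, bc))
  m <- .vcross(n, bc)
  d2 <- c(r * cos(th), r * sin(th) * cos(ph), -r * sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}
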