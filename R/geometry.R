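# Elementary vector geometry shared by all descriptor computations.
# Coordinates are plain numeric length-3 vectors in Angstrom.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise a (near-)zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle between two vectors
#'
#' @param a,b numeric length-3 vectors.
#' @return Angle in degrees in \[0, 180\].
#' @keywords internal
vec_angle <- function(a, b) {
  ua <- .unit(a)
  ub <- .unit(b)
  # atan2 form is numerically stable near 0 and 180 degrees
  atan2(.vnorm(.cross(ua, ub)), sum(ua * ub)) * 180 / pi
}

#' Torsion (dihedral) angle of four points
#'
#' Computes the torsion angle p1-p2-p3-p4 under the IUPAC sign convention:
#' an eclipsed (cis) arrangement gives 0 degrees, an anti (trans) arrangement
#' gives 180 degrees. The result lies in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return Torsion angle in degrees in (-180, 180].
#' @examples
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)) # trans: 180
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))  # cis: 0
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (.vnorm(b1) < 1e-9 || .vnorm(b2) < 1e-9 || .vnorm(b3) < 1e-9)
    stop("degenerate torsion: two consecutive points coincide")
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (.vnorm(n1) < 1e-9 || .vnorm(n2) < 1e-9)
    stop("degenerate torsion: three consecutive points are collinear")
  m1 <- .cross(n1, .unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` degrees about the (unnormalised) `axis`,
#' right-handed.
#'
#' @param axis numeric length-3 direction.
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, angle) {
  u <- .unit(axis)
  th <- angle * pi / 180
  ct <- cos(th)
  st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux * ux * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy * uy * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz * uz * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
}

# Rotate rows of an n x 3 matrix about the axis through `origin`.
.rotate_points <- function(xyz, origin, axis, angle) {
  R <- rotation_about_axis(axis, angle)
  shifted <- sweep(xyz, 2L, origin)
  sweep(shifted %*% t(R), 2L, origin, FUN = "+")
}

#' Place an atom from internal coordinates
#'
#' Natural-extension reference-frame (NeRF) placement: returns the position D
#' such that |C-D| = `bond`, angle(B, C, D) = `angle`, and torsion
#' (A, B, C, D) = `torsion` (IUPAC convention, degrees).
#'
#' @param a,b,c coordinates of the three reference atoms.
#' @param bond bond length C-D in Angstrom.
#' @param angle bond angle B-C-D in degrees.
#' @param torsion torsion A-B-C-D in degrees.
#' @return numeric length-3 coordinate.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d_local <- c(-bond * cos(th),
               bond * sin(th) * cos(ph),
               -bond * sin(th) * sin(ph))
  c + d_local[1L] * bc + d_local[2L] * m + d_local[3L] * n
}

#' Circular distance between two angles
#'
#' @param a,b angles in degrees.
#' @return Smallest absolute angular difference in \[0, 180\].
#' @keywords internal
circular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

# Wrap any angle into (-180, 180].
.wrap180 <- function(a) {
  a <- a %% 360
  a[a > 180] <- a[a > 180] - 360
  a[a <= -180] <- a[a <= -180] + 360
  a
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
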