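# Coordinate conventions used throughout the package (canonical RIGHT knee):
#   +x lateral, +y anterior, +z proximal; units are millimetres.
# The axial (transverse) plane is the fixed xy-plane at constant z; a
# "coronal-plane" rotation is a rotation about an axis parallel to +y.
# Left knees are mirrored (x -> -x) to this frame at ingest.

# geometric identity tolerance (mm) and degeneracy tolerance (mm^2):
# double precision leaves ample headroom at anatomical scale (~1e2 mm)
.TOL_GEOM <- 1e-9
.TOL_AREA <- 1e-6

.vnorm <- function(v) sqrt(sum(v * v))

#' Normalise a 3-vector to unit length
#'
#' @param v numeric length-3 vector.
#' @return unit-length numeric vector.
#' @keywords internal
unit_vector <- function(v) {
  stopifnot(is.numeric(v), length(v) == 3L, all(is.finite(v)))
  n <- .vnorm(v)
  if (n < 1e-12) stop("invalid axis: zero-length direction vector")
  v / n
}

#' Rigid rotation about an arbitrary axis
#'
#' Defines a right-handed rotation by `angle_deg` degrees about the line
#' through `axis_point` along `axis_dir`. With the canonical frame
#' (+x lateral, +y anterior, +z proximal), a positive rotation about +y
#' displaces points distal to the axis point in the medial (-x) direction,
#' i.e. it is a varus rotation for a right knee.
#'
#' @param axis_point numeric length-3, a point on the rotation axis (mm).
#' @param axis_dir numeric length-3 direction of the axis (normalised
#'   internally; zero length is an error).
#' @param angle_deg signed rotation angle in degrees.
#' @return an object of class `rigid_rotation`.
#' @examples
#' r <- rigid_rotation(c(0, 0, 0), c(0, 0, 1), 90)
#' rotate_points(c(10, 0, 0), r)  # -> (0, 10, 0)
#' @export
rigid_rotation <- function(axis_point, axis_dir, angle_deg) {
  stopifnot(is.numeric(axis_point), length(axis_point) == 3L,
            all(is.finite(axis_point)),
            is.numeric(angle_deg), length(angle_deg) == 1L,
            is.finite(angle_deg))
  structure(list(axis_point = as.numeric(axis_point),
                 axis_dir = unit_vector(as.numeric(axis_dir)),
                 angle_deg = as.numeric(angle_deg)),
            class = "rigid_rotation")
}

# Rodrigues rotation matrix for unit axis k and angle in degrees
.rotation_matrix <- function(k, angle_deg) {
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)  # column-major: K %*% v == k x v
  diag(3) * c_ + s_ * K + (1 - c_) * tcrossprod(k)
}

#' Rotate points by a rigid rotation
#'
#' Applies an exact axis-angle (Rodrigues) rotation; pairwise distances are
#' preserved to floating-point precision and a zero angle is the identity.
#'
#' @param points numeric length-3 vector or an n x 3 matrix of points (mm).
#' @param rot a [rigid_rotation()].
#' @return rotated points, same shape as the input.
#' @export
rotate_points <- function(points, rot) {
  stopifnot(inherits(rot, "rigid_rotation"))
  vec_in <- is.null(dim(points))
  p <- if (vec_in) matrix(points, 1, 3) else as.matrix(points)
  stopifnot(ncol(p) == 3L, all(is.finite(p)))
  R <- .rotation_matrix(rot$axis_dir, rot$angle_deg)
  out <- sweep(p, 2, rot$axis_point) %*% t(R)
  out <- sweep(out, 2, rot$axis_point, `+`)
  dimnames(out) <- dimnames(p)
  if (vec_in) drop(out) else out
}

#' Construct a plane from three non-collinear points
#'
#' @param a,b,c numeric length-3 points (mm). The triangle they span must
#'   have area above 1e-6 mm^2.
#' @return an object of class `plane3` with fields `point` and unit `normal`.
#' @export
plane_from_points <- function(a, b, c) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  stopifnot(length(a) == 3L, length(b) == 3L, length(c) == 3L,
            all(is.finite(c(a, b, c))))
  u <- b - a
  v <- c - a
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  if (.vnorm(n) / 2 <= .TOL_AREA)
    stop("degenerate plane: points are collinear or coincident")
  plane3(a, n)
}

#' Plane from a point and a normal direction
#'
#' @param point numeric length-3 point on the plane (mm).
#' @param normal numeric length-3 normal direction (normalised internally).
#' @return an object of class `plane3`.
#' @export
plane3 <- function(point, normal) {
  structure(list(point = as.numeric(point),
                 normal = unit_vector(as.numeric(normal))),
            class = "plane3")
}

#' Signed distance from points to a plane
#'
#' Positive on the side the plane normal points to, in mm.
#'
#' @param points numeric length-3 vector or n x 3 matrix (mm).
#' @param plane a [plane3()].
#' @return numeric vector of signed distances (mm).
#' @export
signed_distance <- function(points, plane) {
  stopifnot(inherits(plane, "plane3"))
  p <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  drop(sweep(p, 2, plane$point) %*% plane$normal)
}

#' Project points into the fixed axial plane
#'
#' Drops the longitudinal (z) coordinate, returning axial (x, y) positions.
#' All TT-TG measurement is performed in this fixed transverse plane.
#'
#' @param points numeric length-3 vector or n x 3 matrix (mm).
#' @return length-2 vector or n x 2 matrix of axial coordinates (mm).
#' @export
project_axial <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3L)
    points[1:2]
  } else {
    as.matrix(points)[, 1:2, drop = FALSE]
  }
}
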