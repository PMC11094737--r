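# Small 3-vector helpers shared across the geometry, force and synthetic modules.
# All angles in degrees at the API surface, radians internally.

DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (n < tol) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `angle` degrees
#' about the (not necessarily unit) vector `axis`.
#'
#' @param axis 3-vector rotation axis.
#' @param angle rotation angle in degrees; positive follows the right-hand
#'   rule about `axis`.
#' @return 3x3 rotation matrix (premultiplies column vectors).
#' @keywords internal
rotation_matrix <- function(axis, angle) {
  u <- unit(axis)
  th <- angle / DEG
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Signed angle (degrees) from a to b about `axis` (right-hand rule),
# measured after projecting both off the axis. Range (-180, 180].
signed_angle_about <- function(a, b, axis) {
  n <- unit(axis)
  ap <- a - sum(a * n) * n
  bp <- b - sum(b * n) * n
  if (vnorm(ap) < 1e-9 || vnorm(bp) < 1e-9)
    stop("degenerate geometry: reference vector (nearly) parallel to axis",
         call. = FALSE)
  ang <- atan2(sum(vcross(ap, bp) * n), sum(ap * bp)) * DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

# Unsigned angle between two vectors, degrees in [0, 180].
angle_between <- function(a, b) {
  acos(clamp1(sum(unit(a) * unit(b)))) * DEG
}
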