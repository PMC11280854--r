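# Orientation math used by the motion segmenter and the synthetic generator.
#
# Convention: intrinsic Z-Y-X (yaw-pitch-roll). The armband delivers fused
# orientation quaternions; the segmenter thresholds changes of the Euler
# angles (roll alpha, pitch beta, yaw gamma), all in degrees.

DEG <- pi / 180

#' Convert Euler angles to a unit quaternion
#'
#' Angles follow the intrinsic Z-Y-X (yaw-pitch-roll) convention:
#' \deqn{q_w = \cos(\alpha/2)\cos(\beta/2)\cos(\gamma/2) +
#'        \sin(\alpha/2)\sin(\beta/2)\sin(\gamma/2)}
#' and correspondingly for \eqn{q_x, q_y, q_z}, with roll \eqn{\alpha},
#' pitch \eqn{\beta} and yaw \eqn{\gamma} in degrees.
#'
#' @param e numeric length-3 vector `c(roll, pitch, yaw)` in degrees
#' @return named numeric vector `c(w, x, y, z)` of unit norm
#' @export
#' @examples
#' euler_to_quaternion(c(0, 0, 0))     # identity rotation
#' euler_to_quaternion(c(180, 0, 0))   # (0, 1, 0, 0)
euler_to_quaternion <- function(e) {
  if (!is.numeric(e) || length(e) != 3L || any(!is.finite(e)))
    stop_invalid("Euler angles must be three finite numbers (degrees)")
  q <- euler_to_quat_m(matrix(e, nrow = 1L))[1L, ]
  names(q) <- c("w", "x", "y", "z")
  q
}

# Vectorised core: `e` is an n x 3 matrix of degrees; returns n x 4 (w,x,y,z).
euler_to_quat_m <- function(e) {
  h <- e * (DEG / 2)
  cr <- cos(h[, 1L]); sr <- sin(h[, 1L])
  cp <- cos(h[, 2L]); sp <- sin(h[, 2L])
  cy <- cos(h[, 3L]); sy <- sin(h[, 3L])
  q <- cbind(
    cr * cp * cy + sr * sp * sy,
    sr * cp * cy - cr * sp * sy,
    cr * sp * cy + sr * cp * sy,
    cr * cp * sy - sr * sp * cy
  )
  q / sqrt(rowSums(q^2))
}

#' Convert a unit quaternion to canonical Euler angles
#'
#' Inverse of [euler_to_quaternion()] under the Z-Y-X convention. Angles are
#' canonicalized to roll, yaw in (-180, 180] and pitch in [-90, 90]. At
#' gimbal lock (|sin(pitch)| within 1e-6 of 1) roll is set to 0 and yaw
#' absorbs the remaining rotation.
#'
#' @param q numeric length-4 vector `c(w, x, y, z)`; normalized internally
#' @return named numeric vector `c(roll, pitch, yaw)` in degrees
#' @export
#' @examples
#' quaternion_to_euler(c(1, 0, 0, 0))  # c(0, 0, 0)
quaternion_to_euler <- function(q) {
  if (!is.numeric(q) || length(q) != 4L || any(!is.finite(q)))
    stop_invalid("quaternion must be four finite numbers")
  if (sum(q^2) < 1e-24)
    stop_invalid("zero-norm quaternion has no orientation")
  e <- quat_to_euler_m(matrix(q, nrow = 1L))[1L, ]
  names(e) <- c("roll", "pitch", "yaw")
  e
}

# Vectorised core: `q` is an n x 4 matrix (rows need not be normalized).
quat_to_euler_m <- function(q) {
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1L]; x <- q[, 2L]; y <- q[, 3L]; z <- q[, 4L]
  sinp <- pmin(1, pmax(-1, 2 * (w * y - z * x)))
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2)) / DEG
  pitch <- asin(sinp) / DEG
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2)) / DEG
  lock <- abs(sinp) >= 1 - 1e-6
  if (any(lock)) {
    # pitch = +/-90: only (yaw -/+ roll) is determined; put it all in yaw.
    roll[lock] <- 0
    yaw[lock] <- 2 * atan2(z[lock], w[lock]) / DEG
  }
  e <- cbind(roll, pitch, yaw)
  e[, c(1L, 3L)] <- canon_angle(e[, c(1L, 3L)])
  e
}

# Map angles (degrees) into (-180, 180].
canon_angle <- function(a) {
  a <- a %% 360
  a - 360 * (a > 180)
}

#' Signed shortest angular difference
#'
#' Returns `b - a` wrapped across +/-180 degrees into the half-open range
#' (-180, 180]; the antipodal tie is broken toward +180.
#'
#' @param a,b angles in degrees (vectorised)
#' @return signed difference(s) in degrees, in (-180, 180]
#' @export
#' @examples
#' angular_difference(359, 1)  # 2
#' angular_difference(0, 180)  # 180
angular_difference <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(a)) || any(!is.finite(b)))
    stop_invalid("angles must be finite numbers")
  d <- (b - a) %% 360
  d - 360 * (d > 180)
}

# --- internal quaternion algebra (used by the synthetic stream) -------------

quat_multiply <- function(p, q) {
  c(p[1L] * q[1L] - p[2L] * q[2L] - p[3L] * q[3L] - p[4L] * q[4L],
    p[1L] * q[2L] + p[2L] * q[1L] + p[3L] * q[4L] - p[4L] * q[3L],
    p[1L] * q[3L] - p[2L] * q[4L] + p[3L] * q[1L] + p[4L] * q[2L],
    p[1L] * q[4L] + p[2L] * q[3L] - p[3L] * q[2L] + p[4L] * q[1L])
}

quat_conjugate <- function(q) c(q[1L], -q[2L], -q[3L], -q[4L])

# Spherical linear interpolation; u in [0,1] may be a vector. Returns
# length(u) x 4 matrix. Falls back to lerp for nearly parallel inputs.
quat_slerp <- function(q0, q1, u) {
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }
  if (d > 1 - 1e-10) {
    out <- outer(1 - u, q0) + outer(u, q1)
  } else {
    th <- acos(pmin(1, d))
    out <- outer(sin((1 - u) * th) / sin(th), q0) + outer(sin(u * th) / sin(th), q1)
  }
  out / sqrt(rowSums(out^2))
}

# Rotate the world vector v into the sensor frame described by rows of q.
quat_rotate_inv <- function(q, v) {
  t(apply(q, 1L, function(qi) {
    r <- quat_multiply(quat_conjugate(qi), quat_multiply(c(0, v), qi))
    r[2:4]
  }))
}
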