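# Quaternion utilities for head-orientation traces.
#
# Quaternions are stored row-wise in an n x 4 matrix with columns (w, x, y, z).
# Axes follow the game-engine convention used by consumer HMDs: Y is up
# (yaw axis), X is the left/right axis (pitch), Z points forward (roll).
# Euler angles are composed intrinsically yaw (Y), then pitch (X), then
# roll (Z), i.e. R = Ry(yaw) %*% Rx(pitch) %*% Rz(roll).

#' Normalize quaternions to unit length
#'
#' @param q numeric matrix, n x 4, columns (w, x, y, z).
#' @return matrix of the same shape with unit-norm rows.
#' @keywords internal
quat_normalize <- function(q) {
  q <- as.matrix(q)
  nrm <- sqrt(rowSums(q^2))
  if (any(nrm < 1e-12)) stop("zero-norm quaternion cannot be normalized")
  q / nrm
}

#' Hamilton product of quaternions
#'
#' Row-wise product `a * b` (rotation `b` applied first when quaternions act
#' on column vectors as R(a %*% b) = R(a) R(b)). Either argument may be a
#' single quaternion (length-4 vector), which is recycled.
#'
#' @param a,b quaternion matrices (n x 4) or length-4 vectors.
#' @return n x 4 quaternion matrix.
#' @keywords internal
quat_multiply <- function(a, b) {
  if (is.vector(a)) a <- matrix(a, nrow = 1)
  if (is.vector(b)) b <- matrix(b, nrow = 1)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L) b <- b[rep(1L, n), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w = w, x = x, y = y, z = z)
}

#' @keywords internal
quat_conjugate <- function(q) {
  if (is.vector(q)) q <- matrix(q, nrow = 1)
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}

#' Quaternion from axis-angle
#'
#' @param axis length-3 axis (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return length-4 quaternion (w, x, y, z).
#' @keywords internal
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  h <- angle_deg * pi / 360
  c(cos(h), sin(h) * axis)
}

#' Geodesic angle between successive or paired orientations
#'
#' Rotation angle (degrees, in [0, 180]) taking orientation `a` to `b`,
#' row-wise. Quaternion double cover is handled by sign alignment, and the
#' angle is computed as 4 atan2(|a - b|, |a + b|), which stays accurate for
#' tiny rotations where the acos form loses precision.
#'
#' @param a,b quaternion matrices (n x 4) or length-4 vectors.
#' @return numeric vector of angles in degrees.
#' @export
quat_angle <- function(a, b) {
  if (is.vector(a)) a <- matrix(a, nrow = 1)
  if (is.vector(b)) b <- matrix(b, nrow = 1)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L) b <- b[rep(1L, n), , drop = FALSE]
  s <- ifelse(rowSums(a * b) < 0, -1, 1)
  b <- b * s
  dm <- sqrt(rowSums((a - b)^2))
  dp <- sqrt(rowSums((a + b)^2))
  unname(4 * atan2(dm, dp) * 180 / pi)
}

#' Spherical linear interpolation between orientation rows
#'
#' Interpolates between `q0[i, ]` and `q1[i, ]` at fraction `t[i]`, taking
#' the shorter arc.
#'
#' @param q0,q1 n x 4 quaternion matrices.
#' @param t interpolation fraction in [0, 1], recycled to n.
#' @return n x 4 unit quaternion matrix.
#' @export
quat_slerp <- function(q0, q1, t) {
  if (is.vector(q0)) q0 <- matrix(q0, nrow = 1)
  if (is.vector(q1)) q1 <- matrix(q1, nrow = 1)
  n <- max(nrow(q0), nrow(q1), length(t))
  if (nrow(q0) == 1L) q0 <- q0[rep(1L, n), , drop = FALSE]
  if (nrow(q1) == 1L) q1 <- q1[rep(1L, n), , drop = FALSE]
  t <- rep_len(t, n)
  d <- rowSums(q0 * q1)
  flip <- d < 0
  q1[flip, ] <- -q1[flip, , drop = FALSE]
  d <- abs(d)
  d <- pmin(d, 1)
  theta <- acos(d)
  out <- matrix(0, n, 4)
  small <- theta < 1e-8
  if (any(small)) {
    # nearly identical orientations: linear blend is exact to first order
    out[small, ] <- (1 - t[small]) * q0[small, , drop = FALSE] +
      t[small] * q1[small, , drop = FALSE]
  }
  if (any(!small)) {
    th <- theta[!small]
    s <- sin(th)
    w0 <- sin((1 - t[!small]) * th) / s
    w1 <- sin(t[!small] * th) / s
    out[!small, ] <- w0 * q0[!small, , drop = FALSE] +
      w1 * q1[!small, , drop = FALSE]
  }
  quat_normalize(out)
}

#' Rotate vectors by quaternions
#'
#' @param q n x 4 quaternion matrix or length-4 vector.
#' @param v length-3 vector rotated by every row of `q`.
#' @return n x 3 matrix of rotated vectors.
#' @keywords internal
quat_rotate <- function(q, v) {
  if (is.vector(q)) q <- matrix(q, nrow = 1)
  qv <- cbind(0, matrix(v, nrow(q), 3, byrow = TRUE))
  r <- quat_multiply(quat_multiply(q, qv), quat_conjugate(q))
  r[, 2:4, drop = FALSE]
}

#' Convert engine Euler angles to quaternions
#'
#' Angles are in degrees: `pitch` about X (left/right axis), `yaw` about Y
#' (up axis), `roll` about Z (forward axis), composed intrinsically in the
#' engine order yaw, pitch, roll.
#'
#' @param euler n x 3 matrix or data frame with columns (pitch, yaw, roll)
#'   in degrees, i.e. rotations about the x, y and z axes.
#' @return n x 4 unit quaternion matrix (w, x, y, z).
#' @export
euler_to_quat <- function(euler) {
  euler <- as.matrix(euler)
  if (ncol(euler) != 3L) stop("euler must have 3 columns (pitch, yaw, roll)")
  hp <- euler[, 1] * pi / 360
  hy <- euler[, 2] * pi / 360
  hr <- euler[, 3] * pi / 360
  qy <- cbind(cos(hy), 0, sin(hy), 0)
  qx <- cbind(cos(hp), sin(hp), 0, 0)
  qz <- cbind(cos(hr), 0, 0, sin(hr))
  quat_multiply(quat_multiply(qy, qx), qz)
}

#' Convert quaternions to engine Euler angles
#'
#' Inverse of [euler_to_quat()]. Near gimbal lock (|pitch| -> 90 deg) yaw
#' and roll are not separately identifiable; the returned decomposition is
#' still a valid one.
#'
#' @param q n x 4 quaternion matrix.
#' @return n x 3 matrix with columns `pitch`, `yaw`, `roll` in degrees.
#' @export
quat_to_euler <- function(q) {
  if (is.vector(q)) q <- matrix(q, nrow = 1)
  q <- quat_normalize(q)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # rotation-matrix elements needed for the yaw-pitch-roll extraction
  r23 <- 2 * (y * z - w * x)            # -sin(pitch)
  r13 <- 2 * (x * z + w * y)            # sin(yaw) cos(pitch)
  r33 <- 1 - 2 * (x^2 + y^2)            # cos(yaw) cos(pitch)
  r21 <- 2 * (x * y + w * z)            # cos(pitch) sin(roll)
  r22 <- 1 - 2 * (x^2 + z^2)            # cos(pitch) cos(roll)
  sp <- pmax(-1, pmin(1, -r23))
  pitch <- asin(sp)
  yaw <- atan2(r13, r33)
  roll <- atan2(r21, r22)
  deg <- 180 / pi
  cbind(pitch = pitch * deg, yaw = yaw * deg, roll = roll * deg)
}

#' Align quaternion signs along a trajectory
#'
#' Flips rows so that consecutive quaternion dot products are non-negative,
#' removing double-cover sign jumps before finite differencing.
#'
#' @param q n x 4 quaternion matrix.
#' @return sign-aligned matrix.
#' @keywords internal
quat_align_signs <- function(q) {
  if (nrow(q) < 2L) return(q)
  d <- rowSums(q[-nrow(q), , drop = FALSE] * q[-1L, , drop = FALSE])
  flips <- cumprod(c(1, ifelse(d < 0, -1, 1)))
  q * flips
}
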