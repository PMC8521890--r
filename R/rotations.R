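# Minimal quaternion toolkit for body orientation tracks.
#
# Quaternions are stored as n x 4 matrices (w, x, y, z) and represent the
# body-to-inertial rotation. The accelerometer measurement rotates inertial
# vectors into the body frame, i.e. applies the conjugate quaternion.

quat <- function(w, x, y, z) cbind(w = w, x = x, y = y, z = z)

quat_normalize <- function(q) q / sqrt(rowSums(q^2))

quat_conj <- function(q) cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])

# Hamilton product, vectorized row-wise (recycles single-row arguments).
quat_mul <- function(p, q) {
  if (nrow(p) == 1 && nrow(q) > 1) p <- p[rep(1, nrow(q)), , drop = FALSE]
  if (nrow(q) == 1 && nrow(p) > 1) q <- q[rep(1, nrow(p)), , drop = FALSE]
  w1 <- p[, 1]; x1 <- p[, 2]; y1 <- p[, 3]; z1 <- p[, 4]
  w2 <- q[, 1]; x2 <- q[, 2]; y2 <- q[, 3]; z2 <- q[, 4]
  quat(
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2
  )
}

quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  quat(cos(angle / 2),
       sin(angle / 2) * axis[1],
       sin(angle / 2) * axis[2],
       sin(angle / 2) * axis[3])
}

# Intrinsic Rz(yaw) %*% Ry(pitch) %*% Rx(roll), body-to-inertial.
quat_from_euler <- function(roll = 0, pitch = 0, yaw = 0) {
  qz <- quat_from_axis_angle(c(0, 0, 1), yaw)
  qy <- quat_from_axis_angle(c(0, 1, 0), pitch)
  qx <- quat_from_axis_angle(c(1, 0, 0), roll)
  quat_mul(quat_mul(qz, qy), qx)
}

# Spherical linear interpolation from the single rotation q0 to q1 at
# fractions s in [0, 1]; returns length(s) x 4.
quat_slerp <- function(q0, q1, s) {
  d <- sum(q0 * q1)
  if (d < 0) {
    q1 <- -q1
    d <- -d
  }
  d <- min(d, 1)
  n <- length(s)
  if (d > 1 - 1e-10) {
    q <- outer(1 - s, q0[1, ]) + outer(s, q1[1, ])
    return(quat_normalize(q))
  }
  th <- acos(d)
  w0 <- sin((1 - s) * th) / sin(th)
  w1 <- sin(s * th) / sin(th)
  quat_normalize(outer(w0, q0[1, ]) + outer(w1, q1[1, ]))
}

# Rotate row-vectors v (n x 3) by quaternions q (n x 4 or 1 x 4).
quat_rotate <- function(q, v) {
  if (nrow(q) == 1 && nrow(v) > 1) q <- q[rep(1, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1 && nrow(q) > 1) v <- v[rep(1, nrow(q)), , drop = FALSE]
  qw <- q[, 1]
  qv <- q[, 2:4, drop = FALSE]
  cross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  t2 <- 2 * cross(qv, v)
  v + qw * t2 + cross(qv, t2)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}
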