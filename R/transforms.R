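# Rigid-transform helpers shared across modules.
# A rigid transform is list(R = 3x3 rotation, t = length-3 translation),
# acting as x -> R %*% x + t, in the ground frame (right-handed, Y-up, meters).

rt <- function(R = diag(3), t = c(0, 0, 0)) {
  list(R = R, t = as.numeric(t))
}

rt_identity <- function() rt()

rt_mul <- function(a, b) {
  # (a o b)(x) = a(b(x))
  rt(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

rt_inv <- function(a) {
  Rt <- t(a$R)
  rt(Rt, as.numeric(-Rt %*% a$t))
}

rt_translate <- function(v) rt(diag(3), v)

# Apply a rigid transform to a single 3-vector or an N x 3 matrix of points.
rt_apply <- function(a, pts) {
  if (is.matrix(pts)) {
    sweep(pts %*% t(a$R), 2, a$t, "+")
  } else {
    as.numeric(a$R %*% as.numeric(pts)) + a$t
  }
}

# Rotation about a unit axis by angle (radians), Rodrigues' formula.
rot_axis_angle <- function(axis, angle) {
  u <- as.numeric(axis)
  n <- sqrt(sum(u^2))
  if (n < 1e-12) stop("rotation axis has zero norm")
  u <- u / n
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)  # column-major: K %*% x = u x x
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

rotation_error <- function(R) {
  max(abs(t(R) %*% R - diag(3)))
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
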