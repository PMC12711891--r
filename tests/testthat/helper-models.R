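# Shared fixtures: tiny skeletal models and an independent 4x4 homogeneous
# matrix oracle for forward kinematics.

vnorm <- skelsynth:::vnorm
unit <- skelsynth:::unit

co_ <- function(name, lo = -pi, hi = pi, default = 0)
  list(name = name, range_min = lo, range_max = hi, default = default)

# Two-body hinge: pelvis fixed to ground at origin, femur below it on a
# single rotation DOF.
toy_hinge_model <- function(axis = c(0, 0, 1), lo = -pi, hi = pi) {
  skeletal_model(
    name = "toy_hinge",
    bodies = list(list(name = "pelvis"),
                  list(name = "femur", leaf_direction = c(0, -1, 0))),
    joints = list(
      list(name = "ground_pelvis", parent_body = "ground", child_body = "pelvis",
           location_in_parent = c(0, 0, 0), location_in_child = c(0, 0, 0),
           dofs = list()),
      list(name = "hip", parent_body = "pelvis", child_body = "femur",
           location_in_parent = c(0, -0.1, 0), location_in_child = c(0, 0, 0),
           dofs = list(list(coordinate = "hip_angle", kind = "rotation", axis = axis)))),
    coordinates = list(co_("hip_angle", lo, hi)),
    markers = list(list(name = "M1", body = "femur", offset = c(0.1, 0, 0))))
}

# Serial chain of n bodies along -Y, each with one hinge about Z, segment
# length L; root joint carries 3 translation DOFs.
toy_chain_model <- function(n = 3, L = 0.5) {
  bodies <- lapply(seq_len(n), function(i) {
    b <- list(name = sprintf("b%d", i))
    if (i == n) b$leaf_direction <- c(0, -1, 0)
    b
  })
  joints <- list(list(
    name = "root", parent_body = "ground", child_body = "b1",
    location_in_parent = c(0, 0, 0), location_in_child = c(0, 0, 0),
    dofs = list(list(coordinate = "tx", kind = "translation", axis = c(1, 0, 0)),
                list(coordinate = "ty", kind = "translation", axis = c(0, 1, 0)),
                list(coordinate = "tz", kind = "translation", axis = c(0, 0, 1)),
                list(coordinate = "q1", kind = "rotation", axis = c(0, 0, 1)))))
  coords <- list(co_("tx", -5, 5), co_("ty", -5, 5), co_("tz", -5, 5), co_("q1"))
  if (n > 1) for (i in 2:n) {
    joints[[i]] <- list(
      name = sprintf("j%d", i), parent_body = sprintf("b%d", i - 1),
      child_body = sprintf("b%d", i),
      location_in_parent = c(0, -L, 0), location_in_child = c(0, 0, 0),
      dofs = list(list(coordinate = sprintf("q%d", i), kind = "rotation",
                       axis = c(0, 0, 1))))
    coords[[length(coords) + 1]] <- co_(sprintf("q%d", i))
  }
  skeletal_model("toy_chain", bodies, joints, coords)
}

# ---- independent FK oracle: explicit 4x4 homogeneous matrices -------------
H_tr <- function(v) { H <- diag(4); H[1:3, 4] <- v; H }
H_rz <- function(a) {
  H <- diag(4); H[1, 1] <- cos(a); H[1, 2] <- -sin(a)
  H[2, 1] <- sin(a); H[2, 2] <- cos(a); H
}
H_rx <- function(a) {
  H <- diag(4); H[2, 2] <- cos(a); H[2, 3] <- -sin(a)
  H[3, 2] <- sin(a); H[3, 3] <- cos(a); H
}
H_apply <- function(H, p) as.numeric(H %*% c(p, 1))[1:3]

# chain FK oracle for toy_chain_model poses
chain_oracle <- function(pose, n, L = 0.5) {
  H <- H_tr(c(pose[["tx"]], pose[["ty"]], pose[["tz"]])) %*% H_rz(pose[["q1"]])
  out <- list(b1 = H)
  if (n > 1) for (i in 2:n) {
    H <- H %*% H_tr(c(0, -L, 0)) %*% H_rz(pose[[sprintf("q%d", i)]])
    out[[sprintf("b%d", i)]] <- H
  }
  out
}

# Minimal hand-built armature (segment bones only) for weight tests.
make_armature <- function(bones_spec) {
  bones <- list()
  b2s <- b2c <- character(0)
  rest <- list()
  for (nm in names(bones_spec)) {
    sp <- bones_spec[[nm]]
    sb <- paste0("seg_", nm); cb <- paste0("ctrl_", nm)
    bones[[cb]] <- list(name = cb, kind = "control", head = sp$head,
                        tail = sp$head + c(0, 0.1, 0), parent = NA,
                        connected = FALSE, rest_rotation = diag(3))
    bones[[sb]] <- list(name = sb, kind = "segment", head = sp$head,
                        tail = sp$tail, parent = cb, connected = FALSE,
                        rest_rotation = diag(3), body = nm)
    b2s[nm] <- sb; b2c[nm] <- cb
    rest[[nm]] <- list(R = diag(3), t = c(0, 0, 0))
  }
  structure(list(bones = bones, body_to_segment = b2s, body_to_control = b2c,
                 rest_global = rest),
            class = "armature")
}

# A collision shape set from world-frame point clouds with identity transforms.
make_shapes <- function(point_sets) {
  shapes <- lapply(names(point_sets), function(nm)
    list(body = nm, hull = convex_hull_3d(point_sets[[nm]]),
         points = point_sets[[nm]]))
  names(shapes) <- names(point_sets)
  class(shapes) <- "collision_shape_set"
  shapes
}

identity_transforms <- function(bodies) {
  out <- lapply(bodies, function(b) list(R = diag(3), t = c(0, 0, 0)))
  names(out) <- bodies
  class(out) <- "body_transforms"
  out
}

# Dense-sampling ray oracle on analytically known shapes: a shape counts if a
# sampled point strictly inside the camera->landmark segment lies inside it
# (membership tested analytically on oriented boxes, independent of the hull
# code), or if the camera itself is inside.
oracle_count <- function(origin, landmark, boxes, n_samples = 4000) {
  tvec <- seq(0, 1 - 1e-6, length.out = n_samples)
  pts <- outer(tvec, landmark - origin)
  pts <- sweep(pts, 2, origin, "+")
  in_box <- function(p, box) {
    q <- t(box$R) %*% (p - box$center)
    all(abs(q) <= box$half + 1e-12)
  }
  sum(vapply(boxes, function(box)
    any(apply(pts, 1, in_box, box = box)), NA))
}

rand_rot <- function() skelsynth:::rot_axis_angle(unit(rnorm(3)), runif(1, 0, 2 * pi))

box_corners <- function(center = c(0, 0, 0), half = c(0.5, 0.5, 0.5)) {
  sweep(as.matrix(expand.grid(x = c(-1, 1) * half[1], y = c(-1, 1) * half[2],
                              z = c(-1, 1) * half[3])), 2, -center)
}
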