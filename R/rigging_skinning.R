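# Rigging: rebuild the skeletal structure as an armature of three bone kinds
# (segment / control / connector), compute distance-based skinning weights and
# deform the mesh by linear blend skinning.

#' Build the three-kind armature from a skeletal model
#'
#' Recreates the skeletal structure of the model as an armature of
#' \describe{
#'   \item{segment bones}{one per body, defined directly by the joint-center
#'     endpoints of the skeletal structure at rest: head at the body's parent
#'     joint center, tail at the next joint center along the kinematic chain.
#'     Leaf bodies (no distal joint) continue from the head for a fixed
#'     distance (`leaf_length`, default 0.12 m) along the rest bone direction
#'     (the body's `leaf_direction` if given, else the direction from the
#'     parent bone's head); branching bodies take the midpoint of their distal
#'     joint centers as tail.}
#'   \item{control bones}{one per body, of fixed length (`control_length`,
#'     default 0.10 m), sharing its head with -- and acting as parent of -- the
#'     segment bone, with rest rotation set to the body's rest rotation. At
#'     pose time the body's simulated global transform is applied to the
#'     control bone and the segment bone follows through the parent link.}
#'   \item{connector bones}{inserted wherever a segment bone's tail and the
#'     next segment bone's head along the chain differ by more than 1e-6 m;
#'     they participate in weight computation and their weights are then moved
#'     to the segment bone they originate from (see [compute_weights()]).}
#' }
#'
#' @param model a `skeletal_model`.
#' @param rest rest-pose `body_transforms`.
#' @param control_length,leaf_length fixed bone lengths in meters.
#' @return an object of class `armature`: list with `bones` (named list;
#'   each bone has `name`, `kind`, `head`, `tail`, `parent`, `connected`,
#'   `rest_rotation`, and for connectors `origin_segment`), `body_to_segment`,
#'   `body_to_control`, and `rest_global` (per-body rest transforms).
#' @export
build_armature <- function(model, rest = rest_transforms(model),
                           control_length = 0.10, leaf_length = 0.12) {
  centers <- joint_centers(model, rest, check = FALSE)
  bn <- body_names(model)
  parent_joint_of <- stats::setNames(
    joint_names(model)[match(bn, vapply(model$joints, `[[`, "", "child_body"))], bn)
  distal_joints_of <- lapply(bn, function(b)
    joint_names(model)[vapply(model$joints, function(j) identical(j$parent_body, b), NA)])
  names(distal_joints_of) <- bn
  parent_body_of <- stats::setNames(
    vapply(model$joints, `[[`, "", "parent_body"),
    vapply(model$joints, `[[`, "", "child_body"))

  bones <- list()
  body_to_segment <- body_to_control <- character(0)
  heads <- tails <- list()

  for (b in bn) {
    head <- centers[[parent_joint_of[[b]]]]
    distal <- distal_joints_of[[b]]
    if (length(distal) == 1) {
      tail <- centers[[distal]]
    } else if (length(distal) > 1) {
      tail <- Reduce(`+`, centers[distal]) / length(distal)
    } else {
      tail <- NULL
    }
    degenerate <- !is.null(tail) && vnorm(tail - head) < 1e-6
    if (is.null(tail) || degenerate) {
      if (degenerate)
        warning(sprintf("body '%s': coincident joint centers; using leaf rule", b),
                call. = FALSE)
      body_def <- model$bodies[[match(b, bn)]]
      dir <- NULL
      if (!is.null(body_def$leaf_direction))
        dir <- as.numeric(rest[[b]]$R %*% body_def$leaf_direction)
      if (is.null(dir)) {
        pb <- parent_body_of[[parent_joint_of[[b]]]]
        if (!identical(pb, "ground") && !is.null(heads[[pb]]))
          dir <- head - heads[[pb]]
      }
      if (is.null(dir) || vnorm(dir) < 1e-9) dir <- as.numeric(rest[[b]]$R %*% c(0, 1, 0))
      tail <- head + leaf_length * unit(dir)
    }
    heads[[b]] <- head; tails[[b]] <- tail
  }

  for (b in bn) {
    cb <- paste0("ctrl_", b)
    sb <- paste0("seg_", b)
    Rb <- rest[[b]]$R
    bones[[cb]] <- list(name = cb, kind = "control", head = heads[[b]],
                        tail = heads[[b]] + as.numeric(Rb %*% c(0, control_length, 0)),
                        parent = NA_character_, connected = FALSE, rest_rotation = Rb)
    bones[[sb]] <- list(name = sb, kind = "segment", head = heads[[b]],
                        tail = tails[[b]], parent = cb, connected = FALSE,
                        rest_rotation = Rb, body = b)
    body_to_segment[b] <- sb
    body_to_control[b] <- cb
  }

  # connectors: for each joint between two modelled bodies, link parent segment
  # bone tail to child segment bone head when they are apart
  for (j in model$joints) {
    if (identical(j$parent_body, "ground")) next
    a <- j$parent_body; b <- j$child_body
    gap <- vnorm(tails[[a]] - heads[[b]])
    if (gap > 1e-6) {
      nm <- sprintf("conn_%s_%s", a, b)
      bones[[nm]] <- list(name = nm, kind = "connector", head = tails[[a]],
                          tail = heads[[b]], parent = body_to_segment[[a]],
                          connected = TRUE, rest_rotation = diag(3),
                          origin_segment = body_to_segment[[a]])
    }
  }

  structure(list(bones = bones, body_to_segment = body_to_segment,
                 body_to_control = body_to_control, rest_global = rest),
            class = "armature")
}

#' @export
print.armature <- function(x, ...) {
  kinds <- table(vapply(x$bones, `[[`, "", "kind"))
  cat(sprintf("<armature> %d bones (%s)\n", length(x$bones),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", ")))
  invisible(x)
}

segment_bone_names <- function(armature) unname(armature$body_to_segment)

# Distance from each row of pts to the segment a--b, vectorized over pts.
point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  d <- sweep(pts, 2, a)
  tpar <- if (len2 < 1e-18) rep(0, nrow(pts)) else pmin(1, pmax(0, (d %*% ab) / len2))
  closest <- outer(as.numeric(tpar), ab)
  sqrt(rowSums((d - closest)^2))
}

#' Compute distance-based skinning weights
#'
#' Emulates automatic distance-based weighting ("bone heat" in spirit): the raw
#' weight of vertex v to bone b is `1 / (d(v, b)^2 + eps)` with `d` the
#' point-to-segment distance to the bone's head--tail segment, for segment
#' *and* connector bones. Entries below `truncate` times the row maximum are
#' set to zero (sparsity), each connector bone's weight is then moved to the
#' segment bone it originates from (emphasizing underweighted branching
#' segments), and rows are renormalized to sum to one.
#'
#' @param mesh a `triangle_mesh`.
#' @param armature an `armature` from [build_armature()].
#' @param eps softening constant (m^2), default 1e-6.
#' @param truncate relative truncation threshold, default 1e-3.
#' @return N x n_segment_bones weight matrix (class `weight_matrix`), columns
#'   named by segment bone.
#' @export
compute_weights <- function(mesh, armature, eps = 1e-6, truncate = 1e-3) {
  if (nrow(mesh$vertices) == 0) stop("empty mesh")
  use <- Filter(function(bone) bone$kind %in% c("segment", "connector"), armature$bones)
  if (length(use) == 0) stop("armature has no segment bones")
  W <- vapply(use, function(bone) {
    1 / (point_segment_distance(mesh$vertices, bone$head, bone$tail)^2 + eps)
  }, numeric(nrow(mesh$vertices)))
  W <- matrix(W, nrow = nrow(mesh$vertices),
              dimnames = list(NULL, vapply(use, `[[`, "", "name")))
  rowmax <- apply(W, 1, max)
  W[W < truncate * rowmax] <- 0
  # move connector weights to their originating segment bone
  for (bone in use) {
    if (bone$kind == "connector") {
      W[, bone$origin_segment] <- W[, bone$origin_segment] + W[, bone$name]
    }
  }
  segs <- segment_bone_names(armature)
  W <- W[, segs, drop = FALSE]
  W <- W / rowSums(W)
  empty <- colSums(W) == 0
  if (any(empty))
    warning(sprintf("segment bones with no weighted vertices: %s",
                    paste(segs[empty], collapse = ", ")), call. = FALSE)
  class(W) <- c("weight_matrix", class(W))
  W
}

#' Per-segment skinning transforms for a pose
#'
#' Each body's simulated global transform is applied to its control bone; the
#' parented segment bone inherits the motion through its rest offset. The
#' resulting skinning transform of segment bone b is
#' `S_b = G_b(pose) o G_b(rest)^-1`, which equals the body transform change
#' `T_body(pose) o T_body(rest)^-1` -- this equality is exactly why the control
#' bone carries the body's rest rotation.
#'
#' @param armature an `armature`.
#' @param transforms posed `body_transforms` from [forward_kinematics()].
#' @return named list of rigid transforms, one per segment bone.
#' @export
skinning_transforms <- function(armature, transforms) {
  out <- list()
  for (b in names(armature$body_to_segment)) {
    pose_tf <- transforms[[b]]
    if (is.null(pose_tf)) stop(sprintf("missing transform for body '%s'", b))
    rest_tf <- armature$rest_global[[b]]
    cb <- armature$bones[[armature$body_to_control[[b]]]]
    # control bone rest transform: the body's rest rotation at the shared head
    K_rest <- rt(cb$rest_rotation, cb$head)
    # posed control bone: body's transform change applied to it
    K_pose <- rt_mul(rt_mul(pose_tf, rt_inv(rest_tf)), K_rest)
    # segment bone rest transform, parented under the control bone
    sbone <- armature$bones[[armature$body_to_segment[[b]]]]
    S_rest <- rt(sbone$rest_rotation, sbone$head)
    offset <- rt_mul(rt_inv(K_rest), S_rest)      # fixed parent-relative offset
    S_pose <- rt_mul(K_pose, offset)
    out[[armature$body_to_segment[[b]]]] <- rt_mul(S_pose, rt_inv(S_rest))
  }
  out
}

#' Deform a mesh by linear blend skinning
#'
#' `v' = sum_b w_vb * S_b(v)`; faces are unchanged.
#'
#' @param mesh a `triangle_mesh` in rest pose.
#' @param weights a `weight_matrix` from [compute_weights()].
#' @param skin named list of per-segment-bone rigid transforms from
#'   [skinning_transforms()].
#' @return the deformed `triangle_mesh` (attributes preserved).
#' @export
deform_mesh <- function(mesh, weights, skin) {
  if (nrow(weights) != nrow(mesh$vertices))
    stop("weight matrix rows must match vertex count")
  if (!all(colnames(weights) %in% names(skin)))
    stop("missing skinning transform for some segment bones")
  V <- matrix(0, nrow(mesh$vertices), 3)
  for (bname in colnames(weights)) {
    w <- weights[, bname]
    nz <- w > 0
    if (!any(nz)) next
    V[nz, ] <- V[nz, ] + w[nz] * rt_apply(skin[[bname]], mesh$vertices[nz, , drop = FALSE])
  }
  out <- mesh
  out$vertices <- V
  out
}

#' Assign each vertex to the body segment with the highest weight
#'
#' Argmax per weight-matrix row; ties break to the lowest column index.
#'
#' @param weights a `weight_matrix` (columns named by segment bone).
#' @param armature optional `armature` used to translate segment-bone names to
#'   body names in the result.
#' @return character vector, one segment-bone name (or body name when
#'   `armature` is given) per vertex.
#' @export
assign_vertices <- function(weights, armature = NULL) {
  idx <- max.col(weights, ties.method = "first")
  seg <- colnames(weights)[idx]
  if (!is.null(armature)) {
    seg_to_body <- stats::setNames(names(armature$body_to_segment),
                                   armature$body_to_segment)
    seg <- unname(seg_to_body[seg])
  }
  seg
}

#' Serialize an armature to JSON for inspection
#' @param armature an `armature`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_armature_json <- function(armature, path) {
  bones <- lapply(armature$bones, function(b) {
    b$rest_rotation <- as.numeric(b$rest_rotation)
    b
  })
  jsonlite::write_json(list(bones = bones,
                            body_to_segment = as.list(armature$body_to_segment),
                            body_to_control = as.list(armature$body_to_control)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
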