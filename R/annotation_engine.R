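# Per-frame ground truth: projected keypoints with depth and ray-cast
# visibility, padded 2D bounding boxes, and kinematics labels.

#' 3D bounding box corners from subsampled mesh vertices
#'
#' Axis-aligned min/max over the vertices at indices 1, 1+step, 1+2*step, ...
#' (every `step`-th vertex; the first vertex is always included). Subsampling
#' trades bounding-box tightness for speed on dense meshes and is recomputed
#' per frame on the deformed mesh.
#'
#' @param mesh a `triangle_mesh` (typically the deformed frame mesh).
#' @param step positive integer vertex stride; default 25.
#' @return 8 x 3 matrix of box corners (all per-axis min/max combinations).
#' @export
bbox_3d <- function(mesh, step = 25) {
  if (nrow(mesh$vertices) == 0) stop("empty mesh")
  if (step < 1) stop("step must be >= 1")
  V <- mesh$vertices[seq(1, nrow(mesh$vertices), by = step), , drop = FALSE]
  lo <- apply(V, 2, min); hi <- apply(V, 2, max)
  as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                        z = c(lo[3], hi[3])))
}

#' Padded 2D bounding box from projected 3D box corners
#'
#' Projects the 8 corners to the camera view, takes the 2D min/max of the
#' corners in front of the camera, and expands the box on all four sides by
#' `padding` pixels (default 25). The box is not clipped to the image bounds;
#' negative top-left coordinates are allowed.
#'
#' @param cam a `camera`.
#' @param corners 8 x 3 matrix from [bbox_3d()].
#' @param padding pixels added on each side.
#' @return list with `x`, `y` (top-left corner), `width`, `height` (pixels).
#' @export
bbox_2d <- function(cam, corners, padding = 25) {
  pr <- project(cam, corners)
  ok <- !pr$behind_camera
  if (!any(ok))
    stop(structure(class = c("skelsynth_bbox_error", "error", "condition"),
                   list(message = "all bounding-box corners behind camera", call = NULL)))
  u <- pr$u[ok]; v <- pr$v[ok]
  list(x = min(u) - padding, y = min(v) - padding,
       width = diff(range(u)) + 2 * padding,
       height = diff(range(v)) + 2 * padding)
}

#' Build rigid per-segment collision shapes
#'
#' For each body segment, the convex hull of the mesh vertices assigned to it
#' (highest skinning weight, see [assign_vertices()]), expressed in the body's
#' local rest frame. Built once per avatar: the shapes are rigid and only
#' translate/rotate with the body afterwards, so they drift from the deformed
#' skin in extreme poses -- like the engine colliders they emulate. Segments
#' with fewer than 4 non-coplanar vertices are flagged degenerate and excluded
#' from ray casting with a warning.
#'
#' @param mesh the rest-pose `triangle_mesh`.
#' @param assignment character vector: body name per vertex.
#' @param rest rest-pose `body_transforms`.
#' @return object of class `collision_shape_set`: named list of
#'   `list(body, hull, points)` entries (local-frame hull + its point set).
#' @export
build_collision_shapes <- function(mesh, assignment, rest) {
  if (length(assignment) != nrow(mesh$vertices))
    stop("assignment must cover every vertex")
  shapes <- list()
  for (b in unique(assignment)) {
    inv <- rt_inv(rest[[b]])
    local <- rt_apply(inv, mesh$vertices[assignment == b, , drop = FALSE])
    hull <- convex_hull_3d(local)
    if (isTRUE(hull$degenerate))
      warning(sprintf("segment '%s': degenerate collision shape (excluded from ray casting)", b),
              call. = FALSE)
    shapes[[b]] <- list(body = b, hull = hull, points = local)
  }
  structure(shapes, class = "collision_shape_set")
}

#' Count collision shapes entered by the camera-to-landmark ray
#'
#' Casts a ray from the camera to the landmark and counts how many collision
#' shapes the ray enters strictly before reaching the landmark: a shape counts
#' when its entry intersection lies at distance `< ||landmark - camera|| - eps`
#' along the ray (eps = 1e-9 of the ray length, at least 1e-9 m); a shape
#' containing the camera counts as entered at distance 0. A landmark inside
#' its own body's shape therefore yields at least N = 1, and a ray grazing
#' between shapes can yield N = 0.
#'
#' @param cam a `camera` (or a bare 3-vector camera position).
#' @param landmark 3-vector (m).
#' @param shapes a `collision_shape_set`.
#' @param transforms current-pose `body_transforms`.
#' @return non-negative integer N.
#' @export
count_colliders <- function(cam, landmark, shapes, transforms) {
  origin <- if (inherits(cam, "camera")) cam$position else as.numeric(cam)
  ray <- landmark - origin
  L <- vnorm(ray)
  if (L < 1e-12) return(0L)
  d <- ray / L
  eps <- 1e-9 * max(1, L)
  n <- 0L
  for (s in shapes) {
    if (isTRUE(s$hull$degenerate)) next
    tf <- transforms[[s$body]]
    if (is.null(tf)) stop(sprintf("missing transform for body '%s'", s$body))
    inv <- rt_inv(tf)
    o_local <- rt_apply(inv, origin)
    d_local <- as.numeric(inv$R %*% d)
    iv <- ray_hull_interval(s$hull, o_local, d_local)
    if (is.null(iv)) next
    entry <- max(iv[1], 0)
    if (iv[2] >= entry && entry < L - eps) n <- n + 1L
  }
  n
}

#' Visibility label from a collider count
#'
#' `visibility = 1 / (1 + N)`: 1 means no occluder between camera and
#' landmark, values near 0 mean strong occlusion. The label lives in the
#' half-open interval (0, 1].
#'
#' @param N non-negative integer collider count (vectorized).
#' @return numeric in (0, 1].
#' @export
visibility <- function(N) {
  if (any(N < 0)) stop("N must be non-negative")
  1 / (1 + N)
}

#' Annotate one frame
#'
#' Produces the full per-image ground truth: one keypoint per joint center
#' (kind `joint`), per body-frame origin (kind `body`) and per virtual marker
#' (kind `marker`), each with pixel coordinates, Euclidean depth and ray-cast
#' visibility; the padded 2D bounding box of the subsampled deformed mesh; and
#' the generalized-coordinate labels of the pose.
#'
#' @param model a `skeletal_model`.
#' @param pose named pose vector.
#' @param mesh_deformed the deformed frame `triangle_mesh`.
#' @param cam a `camera`.
#' @param shapes a `collision_shape_set` (for visibility).
#' @param transforms posed `body_transforms`; computed from the pose if NULL.
#' @param step bounding-box vertex stride (default 25).
#' @param padding bounding-box padding in pixels (default 25).
#' @param image_id optional image identifier stored on the record.
#' @return object of class `frame_annotation`: list with `image_id`, `bbox`,
#'   `keypoints` (data.frame: name, kind, u, v, depth, visibility,
#'   behind_camera) and `kinematics` (named numeric).
#' @export
annotate_frame <- function(model, pose, mesh_deformed, cam, shapes,
                           transforms = NULL, step = 25, padding = 25,
                           image_id = NA_character_) {
  if (is.null(transforms)) transforms <- forward_kinematics(model, pose)
  jc <- joint_centers(model, transforms, check = FALSE)
  bo <- lapply(transforms, `[[`, "t")
  mk <- marker_positions(model, transforms)
  pts <- rbind(do.call(rbind, jc), do.call(rbind, bo), do.call(rbind, mk))
  kinds <- c(rep("joint", length(jc)), rep("body", length(bo)), rep("marker", length(mk)))
  names_ <- paste(kinds, c(names(jc), names(bo), names(mk)), sep = "_")
  pr <- project(cam, pts)
  dep <- point_depth(cam, pts)
  vis <- vapply(seq_len(nrow(pts)), function(i)
    visibility(count_colliders(cam, pts[i, ], shapes, transforms)), 0)
  kp <- data.frame(name = names_, kind = kinds, u = pr$u, v = pr$v,
                   depth = dep, visibility = vis,
                   behind_camera = pr$behind_camera,
                   stringsAsFactors = FALSE, row.names = NULL)
  bbox <- bbox_2d(cam, bbox_3d(mesh_deformed, step = step), padding = padding)
  structure(list(image_id = image_id, bbox = bbox, keypoints = kp,
                 kinematics = pose[coordinate_names(model)]),
            class = "frame_annotation")
}
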