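#' Construct a skeletal model
#'
#' A skeletal model is a tree of rigid body segments connected by joints whose
#' degrees of freedom are bounded generalized coordinates (joint angles in
#' radians, root translations in meters), plus virtual markers fixed in body
#' frames. The ground frame is right-handed, Y-up, in meters. The model plays
#' the role of a simplified OpenSim-style musculoskeletal model: it defines the
#' pose space, the landmark set, and (through its rest pose) the frame in which
#' the avatar mesh is built and rigged.
#'
#' @param name model name.
#' @param bodies list of body descriptors; each a list with `name` and an
#'   optional `leaf_direction` (unit 3-vector in the body frame used to extend
#'   the segment bone of a leaf body, see [build_armature()]).
#' @param joints list of joints; each a list with `name`, `parent_body`
#'   (`"ground"` for the root joint), `child_body`, `location_in_parent`,
#'   `location_in_child` (3-vectors, meters, in the respective body frames) and
#'   `dofs`, an ordered list of `list(coordinate=, kind=, axis=)` entries with
#'   `kind` either `"rotation"` or `"translation"` and `axis` a unit 3-vector.
#'   Rotation DOFs compose intrinsically in the listed order.
#' @param coordinates list of `list(name=, range_min=, range_max=, default=)`.
#' @param markers list of `list(name=, body=, offset=)` virtual markers.
#' @return an object of class `skeletal_model`.
#' @seealso [load_model()], [forward_kinematics()], [demo_model()]
#' @export
skeletal_model <- function(name, bodies, joints, coordinates, markers = list()) {
  model <- structure(
    list(name = name, format_version = "1.0",
         bodies = bodies, joints = joints,
         coordinates = coordinates, markers = markers),
    class = "skeletal_model")
  validate_model(model)
  model
}

#' @export
print.skeletal_model <- function(x, ...) {
  cat(sprintf("<skeletal_model> %s: %d bodies, %d joints, %d coordinates, %d markers\n",
              x$name, length(x$bodies), length(x$joints),
              length(x$coordinates), length(x$markers)))
  invisible(x)
}

body_names <- function(model) vapply(model$bodies, `[[`, "", "name")

#' Names of the model's generalized coordinates
#' @param model a `skeletal_model`.
#' @return character vector in model definition order.
#' @export
coordinate_names <- function(model) vapply(model$coordinates, `[[`, "", "name")

joint_names <- function(model) vapply(model$joints, `[[`, "", "name")

marker_names <- function(model) vapply(model$markers, `[[`, "", "name")

#' Coordinate ranges as a matrix
#' @param model a `skeletal_model`.
#' @return matrix with columns `min`, `max`, `default`; one row per coordinate.
#' @export
coordinate_ranges <- function(model) {
  m <- cbind(
    min = vapply(model$coordinates, function(co) co$range_min, 0),
    max = vapply(model$coordinates, function(co) co$range_max, 0),
    default = vapply(model$coordinates, function(co) co$default, 0))
  rownames(m) <- coordinate_names(model)
  m
}

#' Default (rest) pose of a model
#'
#' @param model a `skeletal_model`.
#' @return named numeric vector, one value per coordinate, at the defaults.
#' @export
default_pose <- function(model) {
  p <- vapply(model$coordinates, function(co) co$default, 0)
  names(p) <- coordinate_names(model)
  p
}

# The root joint is the unique joint whose parent is ground.
root_joint <- function(model) {
  idx <- which(vapply(model$joints, function(j) identical(j$parent_body, "ground"), NA))
  model$joints[[idx]]
}

#' Validate a skeletal model
#'
#' Checks the structural invariants: the joints connect the bodies into a tree
#' rooted at a single root body attached to ground; every non-root body is the
#' child of exactly one joint; coordinate names are unique and every joint DOF
#' references an existing coordinate; DOF axes have unit norm; coordinate
#' ranges are non-degenerate and contain the default; marker bodies exist.
#'
#' @param model a `skeletal_model`.
#' @return the model, invisibly; signals a condition of class
#'   `skelsynth_topology_error` or `skelsynth_format_error` on violation.
#' @export
validate_model <- function(model) {
  fail <- function(msg, class = "skelsynth_topology_error") {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  bn <- body_names(model)
  if (anyDuplicated(bn)) fail(sprintf("duplicate body name: %s", bn[duplicated(bn)][1]))
  cn <- coordinate_names(model)
  if (anyDuplicated(cn)) fail(sprintf("duplicate coordinate name: %s", cn[duplicated(cn)][1]),
                              "skelsynth_format_error")
  for (co in model$coordinates) {
    if (!(co$range_min < co$range_max))
      fail(sprintf("coordinate '%s': range_min must be < range_max", co$name),
           "skelsynth_format_error")
    if (co$default < co$range_min || co$default > co$range_max)
      fail(sprintf("coordinate '%s': default outside [range_min, range_max]", co$name),
           "skelsynth_format_error")
  }
  n_root <- 0L
  child_count <- stats::setNames(integer(length(bn)), bn)
  for (j in model$joints) {
    if (!identical(j$parent_body, "ground") && !(j$parent_body %in% bn))
      fail(sprintf("joint '%s' references unknown parent body '%s'", j$name, j$parent_body))
    if (!(j$child_body %in% bn))
      fail(sprintf("joint '%s' references unknown child body '%s'", j$name, j$child_body))
    if (identical(j$parent_body, "ground")) n_root <- n_root + 1L
    child_count[j$child_body] <- child_count[j$child_body] + 1L
    if (length(j$dofs) > 6L)
      fail(sprintf("joint '%s' has more than 6 DOFs", j$name), "skelsynth_format_error")
    for (d in j$dofs) {
      if (!(d$coordinate %in% cn))
        fail(sprintf("joint '%s' DOF references unknown coordinate '%s'", j$name, d$coordinate),
             "skelsynth_format_error")
      if (!d$kind %in% c("rotation", "translation"))
        fail(sprintf("joint '%s': DOF kind must be rotation or translation", j$name),
             "skelsynth_format_error")
      if (abs(vnorm(as.numeric(d$axis)) - 1) > 1e-6)
        fail(sprintf("joint '%s': DOF axis for '%s' is not unit-norm", j$name, d$coordinate),
             "skelsynth_format_error")
    }
  }
  if (n_root != 1L)
    fail(sprintf("model must have exactly one joint attached to ground (found %d)", n_root))
  if (any(child_count != 1L)) {
    bad <- names(child_count)[child_count != 1L][1]
    fail(sprintf("body '%s' is the child of %d joints (must be exactly 1)",
                 bad, child_count[bad]))
  }
  # acyclicity: walking parents from every body must reach ground
  parent_of <- stats::setNames(
    vapply(model$joints, `[[`, "", "parent_body"),
    vapply(model$joints, `[[`, "", "child_body"))
  for (b in bn) {
    cur <- b
    for (step in seq_len(length(bn) + 1L)) {
      cur <- parent_of[[cur]]
      if (identical(cur, "ground")) break
      if (step > length(bn)) fail(sprintf("cycle detected through body '%s'", b))
    }
  }
  for (mk in model$markers) {
    if (!(mk$body %in% bn))
      fail(sprintf("marker '%s' references unknown body '%s'", mk$name, mk$body))
  }
  invisible(model)
}

#' Save a skeletal model to a JSON file
#'
#' The on-disk format is a documented JSON subset carrying exactly the model
#' fields (bodies, joints with ordered DOFs, coordinate ranges, markers) plus a
#' `format_version` field. It stands in for an OpenSim `.osim` file; only the
#' topology, DOFs, ranges and markers that drive this package are represented.
#'
#' @param model a `skeletal_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a skeletal model from a JSON file
#'
#' @param path path to a model JSON file written by [save_model()] (or by hand
#'   following the same schema).
#' @return a validated `skeletal_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      stop(structure(class = c("skelsynth_format_error", "error", "condition"),
                     list(message = sprintf("failed to parse model file '%s': %s",
                                            path, conditionMessage(e)),
                          call = NULL)))
    })
  num <- function(x) as.numeric(unlist(x))
  bodies <- lapply(raw$bodies, function(b) {
    out <- list(name = b$name)
    if (!is.null(b$leaf_direction)) out$leaf_direction <- num(b$leaf_direction)
    out
  })
  joints <- lapply(raw$joints, function(j) {
    list(name = j$name, parent_body = j$parent_body, child_body = j$child_body,
         location_in_parent = num(j$location_in_parent),
         location_in_child = num(j$location_in_child),
         dofs = lapply(j$dofs, function(d)
           list(coordinate = d$coordinate, kind = d$kind, axis = num(d$axis))))
  })
  coords <- lapply(raw$coordinates, function(co)
    list(name = co$name, range_min = as.numeric(co$range_min),
         range_max = as.numeric(co$range_max), default = as.numeric(co$default)))
  markers <- lapply(raw$markers, function(mk)
    list(name = mk$name, body = mk$body, offset = num(mk$offset)))
  skeletal_model(name = raw$name %||% "unnamed", bodies = bodies, joints = joints,
                 coordinates = coords, markers = markers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_pose <- function(model, pose, strict = FALSE) {
  cn <- coordinate_names(model)
  missing <- setdiff(cn, names(pose))
  if (length(missing) > 0)
    stop(structure(class = c("skelsynth_incomplete_pose", "error", "condition"),
                   list(message = sprintf("pose is missing coordinates: %s",
                                          paste(missing, collapse = ", ")),
                        call = NULL)))
  vals <- pose[cn]
  if (any(!is.finite(vals))) stop("pose contains non-finite values")
  rng <- coordinate_ranges(model)
  out <- vals < rng[, "min"] - 1e-12 | vals > rng[, "max"] + 1e-12
  if (any(out)) {
    msg <- sprintf("pose values out of coordinate range: %s",
                   paste(cn[out], collapse = ", "))
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  vals
}

joint_local_transform <- function(joint, pose) {
  tf <- rt_translate(joint$location_in_parent)
  for (d in joint$dofs) {
    q <- pose[[d$coordinate]]
    step <- if (identical(d$kind, "rotation")) {
      rt(rot_axis_angle(d$axis, q), c(0, 0, 0))
    } else {
      rt_translate(as.numeric(d$axis) * q)
    }
    tf <- rt_mul(tf, step)
  }
  rt_mul(tf, rt_translate(-as.numeric(joint$location_in_child)))
}

#' Forward kinematics: global body transforms for a pose
#'
#' Composes joint transforms from ground down the tree. For each joint, the
#' child body transform is
#' `parent o translate(location_in_parent) o DOF transforms (in order) o
#' translate(-location_in_child)`; rotation DOFs are intrinsic rotations about
#' the per-DOF axes, translation DOFs translate along them.
#'
#' @param model a `skeletal_model`.
#' @param pose named numeric vector covering every model coordinate
#'   (radians / meters).
#' @param strict reject out-of-range coordinate values instead of warning.
#' @return a named list (class `body_transforms`), one rigid transform
#'   `list(R =, t =)` per body, in ground frame.
#' @export
forward_kinematics <- function(model, pose, strict = FALSE) {
  vals <- check_pose(model, pose, strict = strict)
  pose <- as.list(vals)
  transforms <- list(ground = rt_identity())
  remaining <- model$joints
  while (length(remaining) > 0) {
    ready <- vapply(remaining, function(j) j$parent_body %in% names(transforms), NA)
    if (!any(ready)) stop("unresolvable joint ordering (cycle?)")
    for (j in remaining[ready]) {
      transforms[[j$child_body]] <- rt_mul(transforms[[j$parent_body]],
                                           joint_local_transform(j, pose))
    }
    remaining <- remaining[!ready]
  }
  transforms <- transforms[body_names(model)]
  class(transforms) <- "body_transforms"
  transforms
}

#' Rest-pose body transforms
#'
#' Forward kinematics evaluated at the model's default pose. This is the frame
#' in which the avatar mesh is generated and the armature is rigged.
#'
#' @param model a `skeletal_model`.
#' @return a `body_transforms` list.
#' @export
rest_transforms <- function(model) {
  forward_kinematics(model, default_pose(model))
}

#' Joint center positions in the ground frame
#'
#' The center of a joint is its `location_in_parent` carried into the ground
#' frame by the parent body transform; by construction of the kinematics this
#' equals the child-side computation (`location_in_child` through the child
#' transform) for purely rotational joints, and the two are checked to agree.
#'
#' @param model a `skeletal_model`.
#' @param transforms a `body_transforms` list from [forward_kinematics()].
#' @param check verify parent-side/child-side agreement (skipped automatically
#'   for joints with translation DOFs, where the two sides differ by the
#'   translation).
#' @return named list of 3-vectors, one per joint.
#' @export
joint_centers <- function(model, transforms, check = TRUE) {
  centers <- list()
  for (j in model$joints) {
    parent_tf <- if (identical(j$parent_body, "ground")) rt_identity()
                 else transforms[[j$parent_body]]
    if (is.null(parent_tf)) stop(sprintf("missing transform for body '%s'", j$parent_body))
    c_parent <- rt_apply(parent_tf, j$location_in_parent)
    has_translation <- any(vapply(j$dofs, function(d) identical(d$kind, "translation"), NA))
    if (check && !has_translation) {
      c_child <- rt_apply(transforms[[j$child_body]], j$location_in_child)
      if (vnorm(c_parent - c_child) > 1e-9)
        stop(sprintf("joint '%s': parent- and child-side centers disagree", j$name))
    }
    centers[[j$name]] <- c_parent
  }
  centers
}

#' Virtual marker positions in the ground frame
#'
#' @param model a `skeletal_model`.
#' @param transforms a `body_transforms` list.
#' @return named list of 3-vectors, one per marker.
#' @export
marker_positions <- function(model, transforms) {
  out <- list()
  for (mk in model$markers) {
    tf <- transforms[[mk$body]]
    if (is.null(tf)) stop(sprintf("marker '%s': missing transform for body '%s'",
                                  mk$name, mk$body))
    out[[mk$name]] <- rt_apply(tf, mk$offset)
  }
  out
}

#' Sample a random pose uniformly within coordinate ranges
#'
#' Each generalized coordinate is drawn independently from the uniform
#' distribution on its `[range_min, range_max]` interval, emulating the
#' random-kinematics subset of the dataset. Root translation coordinates
#' (translation DOFs of the joint attached to ground) are by default held at
#' their model defaults so the avatar stays at the camera target.
#'
#' @param model a `skeletal_model`.
#' @param translation_policy `"fixed"` (root translations at default) or
#'   `"sampled"` (drawn like every other coordinate).
#' @return a named numeric pose vector. Uses the current R RNG stream; seed
#'   with [set.seed()] for reproducibility.
#' @export
random_pose <- function(model, translation_policy = c("fixed", "sampled")) {
  translation_policy <- match.arg(translation_policy)
  rng <- coordinate_ranges(model)
  cn <- rownames(rng)
  vals <- stats::runif(length(cn), rng[, "min"], rng[, "max"])
  names(vals) <- cn
  if (translation_policy == "fixed") {
    rj <- root_joint(model)
    fixed <- vapply(Filter(function(d) identical(d$kind, "translation"), rj$dofs),
                    `[[`, "", "coordinate")
    vals[fixed] <- rng[fixed, "default"]
  }
  vals
}
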