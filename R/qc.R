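# Quality control: bounding-box step sensitivity, kinematics distribution
# summaries, and a generic keypoint-set distance utility.

#' Bounding-box vertex-step sensitivity experiment
#'
#' Measures how much the 2D bounding box shrinks when it is computed from
#' every `step`-th mesh vertex instead of every vertex. For each of `n_images`
#' seeded random poses and cameras of the given avatar, the unpadded 2D
#' bounding-box width and height are computed at each step and at step 1, and
#' the absolute differences are recorded (they are one-sided: the subsampled
#' box is never larger).
#'
#' @param model a `skeletal_model` (default [demo_model()]).
#' @param morphology a [morphology_params()] for the avatar.
#' @param n_images number of random pose/camera samples (default 100).
#' @param steps integer vector of vertex strides (default 5, 10, ..., 50).
#' @param seed RNG seed.
#' @param cam_ranges a [camera_ranges()] list (default 1024 x 1024 images).
#' @return object of class `step_experiment`: list with `differences` (long
#'   data.frame: image, step, dwidth, dheight), `summary` (per step: median
#'   and max over both dimensions) and `median_overall` (median of all
#'   absolute width/height differences across steps), in pixels.
#' @export
bbox_step_experiment <- function(model = demo_model(),
                                 morphology = morphology_params(),
                                 n_images = 100, steps = seq(5, 50, by = 5),
                                 seed = 1, cam_ranges = camera_ranges()) {
  if (n_images < 1) stop("n_images must be >= 1")
  rest <- rest_transforms(model)
  mesh <- generate_avatar(model, morphology, rest)
  armature <- build_armature(model, rest)
  weights <- compute_weights(mesh, armature)
  set.seed(seed)
  rows <- vector("list", n_images * length(steps))
  k <- 0L
  for (i in seq_len(n_images)) {
    pose <- random_pose(model)
    transforms <- forward_kinematics(model, pose)
    deformed <- deform_mesh(mesh, weights, skinning_transforms(armature, transforms))
    cam <- sample_camera(colMeans(deformed$vertices), cam_ranges)
    ref <- bbox_2d(cam, bbox_3d(deformed, step = 1), padding = 0)
    for (s in steps) {
      bb <- bbox_2d(cam, bbox_3d(deformed, step = s), padding = 0)
      k <- k + 1L
      rows[[k]] <- data.frame(image = i, step = s,
                              dwidth = abs(ref$width - bb$width),
                              dheight = abs(ref$height - bb$height))
    }
  }
  diffs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(diffs, diffs$step), function(d)
    data.frame(step = d$step[1],
               median = stats::median(c(d$dwidth, d$dheight)),
               max = max(d$dwidth, d$dheight))))
  rownames(summ) <- NULL
  structure(list(differences = diffs, summary = summ,
                 median_overall = stats::median(c(diffs$dwidth, diffs$dheight)),
                 n_vertices = nrow(mesh$vertices)),
            class = "step_experiment")
}

#' @export
print.step_experiment <- function(x, ...) {
  cat(sprintf("<step_experiment> %d-vertex avatar; median |Ddim| overall: %.2f px\n",
              x$n_vertices, x$median_overall))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Per-coordinate histograms and uniformity statistics
#'
#' Histograms are bounded to each coordinate's valid range; the
#' Kolmogorov-Smirnov statistic is computed against the uniform distribution
#' on that range. Random-generated kinematics should be near-uniform; real
#' motion concentrates around common postures.
#'
#' @param frames list of pose vectors, or a frames x coordinates matrix.
#' @param model the `skeletal_model` defining coordinate ranges.
#' @param bins number of histogram bins (default 20).
#' @return named list per coordinate: `list(breaks, counts, ks_statistic)`.
#' @export
coordinate_distributions <- function(frames, model, bins = 20) {
  if (is.list(frames)) frames <- do.call(rbind, frames)
  if (nrow(frames) < 2) stop("need at least 2 frames")
  rng <- coordinate_ranges(model)
  out <- list()
  for (cn in rownames(rng)) {
    if (!(cn %in% colnames(frames))) next
    x <- frames[, cn]
    breaks <- seq(rng[cn, "min"], rng[cn, "max"], length.out = bins + 1)
    counts <- hist(pmin(pmax(x, rng[cn, "min"]), rng[cn, "max"]),
                   breaks = breaks, plot = FALSE)$counts
    ks <- if (stats::sd(x) == 0) 1 else
      unname(suppressWarnings(
        stats::ks.test(x, "punif", rng[cn, "min"], rng[cn, "max"])$statistic))
    out[[cn]] <- list(breaks = breaks, counts = counts, ks_statistic = ks)
  }
  out
}

#' Euclidean pixel distances between two keypoint sets
#'
#' Measurement machinery for comparing externally detected keypoints against
#' the generated annotations: per shared keypoint name, the Euclidean distance
#' between the two (u, v) positions.
#'
#' @param setA,setB data.frames with columns `name`, `u`, `v` (or named N x 2
#'   matrices).
#' @return list with `distances` (named numeric, pixels), `missing_in_A`,
#'   `missing_in_B` (character vectors of unshared names).
#' @export
keypoint_set_distance <- function(setA, setB) {
  as_tab <- function(s) {
    if (is.matrix(s)) data.frame(name = rownames(s), u = s[, 1], v = s[, 2])
    else s
  }
  a <- as_tab(setA); b <- as_tab(setB)
  shared <- intersect(a$name, b$name)
  if (length(shared) == 0) stop("keypoint sets share no names")
  ia <- match(shared, a$name); ib <- match(shared, b$name)
  d <- sqrt((a$u[ia] - b$u[ib])^2 + (a$v[ia] - b$v[ib])^2)
  names(d) <- shared
  list(distances = d,
       missing_in_A = setdiff(b$name, a$name),
       missing_in_B = setdiff(a$name, b$name))
}
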