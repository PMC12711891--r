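# Orchestration: permute poses x cameras x morphologies x appearance, render
# and annotate every planned frame, and write the dataset tree
# (images/, silhouettes/, segments/, annotations/).

#' Dataset generation configuration
#'
#' @param output_dir output directory (created if missing).
#' @param subset `"random"` (poses drawn uniformly within coordinate ranges)
#'   or `"real"` (poses taken from motion trials).
#' @param model a `skeletal_model` (default [demo_model()]).
#' @param n_images number of images to generate.
#' @param n_poses number of distinct poses; images cycle over them (default
#'   `n_images`). For `"real"` subsets the poses are drawn from the trials via
#'   [extract_equal_frames()].
#' @param motion list of `motion_trial` objects or .mot file paths (required
#'   for subset `"real"`).
#' @param morphologies list of [morphology_params()]; default the ten-way
#'   sweep: female/male crossed with shape -2, -1, 0, 1, 2.
#' @param cam_ranges a [camera_ranges()] list.
#' @param settings a [render_settings()] list.
#' @param backgrounds list of background specs cycled over images (default the
#'   settings background only).
#' @param step,padding bounding-box vertex stride and padding (pixels).
#' @param seed master seed; every random draw in the pipeline derives from it.
#' @param resume skip images whose files already exist.
#' @return a `dataset_config` list.
#' @export
dataset_config <- function(output_dir, subset = c("random", "real"),
                           model = demo_model(), n_images = 10,
                           n_poses = n_images, motion = NULL,
                           morphologies = default_morphologies(),
                           cam_ranges = camera_ranges(),
                           settings = render_settings(),
                           backgrounds = NULL,
                           step = 25, padding = 25, seed = 42,
                           resume = FALSE) {
  subset <- match.arg(subset)
  if (n_images < 1) stop("n_images must be >= 1")
  if (subset == "real" && (is.null(motion) || length(motion) == 0))
    stop("subset 'real' requires motion trials or .mot paths")
  if (n_poses > n_images) n_poses <- n_images
  structure(list(output_dir = output_dir, subset = subset, model = model,
                 n_images = as.integer(n_images), n_poses = as.integer(n_poses),
                 motion = motion, morphologies = morphologies,
                 cam_ranges = cam_ranges, settings = settings,
                 backgrounds = backgrounds, step = step, padding = padding,
                 seed = as.integer(seed), resume = resume),
            class = "dataset_config")
}

#' The ten-way default morphology sweep
#'
#' Female and male variants at shape values -2, -1, 0, 1 and 2 (the
#' recommended range of statistical body-shape parameters).
#'
#' @param mesh_resolution target vertex count per avatar.
#' @return list of 10 [morphology_params()].
#' @export
default_morphologies <- function(mesh_resolution = 7500) {
  out <- list()
  for (sex in c("female", "male"))
    for (b in -2:2)
      out[[length(out) + 1]] <- morphology_params(sex, b, mesh_resolution)
  out
}

resolve_motion <- function(config) {
  lapply(config$motion, function(m) {
    if (inherits(m, "motion_trial")) m
    else read_mot(m, model = config$model, source = "real")
  })
}

#' Plan the permutation of poses, cameras, morphologies and appearance
#'
#' Deterministic given the master seed. Poses: for `"real"` subsets,
#' (trial, frame) pairs via [extract_equal_frames()]; for `"random"`, one pose
#' seed per distinct pose. Images cycle over the poses; morphologies are
#' assigned round-robin; camera and appearance seeds are drawn per image from
#' the master seed; backgrounds cycle.
#'
#' @param config a [dataset_config()].
#' @return data.frame of class `permutation_plan`, one row per image:
#'   `image_id` (zero-padded, sequential), `trial`, `frame`, `pose_seed`,
#'   `morphology`, `camera_seed`, `appearance_seed`, `background`.
#' @export
plan_permutations <- function(config) {
  n <- config$n_images
  set.seed(config$seed)
  if (config$subset == "real") {
    trials <- resolve_motion(config)
    frames <- extract_equal_frames(trials, config$n_poses)
    pose_tab <- data.frame(trial = frames$trial, frame = frames$frame,
                           pose_seed = NA_integer_)
  } else {
    pose_tab <- data.frame(trial = NA_character_, frame = NA_integer_,
                           pose_seed = sample.int(.Machine$integer.max, config$n_poses))
  }
  pose_idx <- ((seq_len(n) - 1L) %% nrow(pose_tab)) + 1L
  n_bg <- max(1L, length(config$backgrounds))
  plan <- data.frame(
    image_id = sprintf("%06d", seq_len(n)),
    pose_tab[pose_idx, , drop = FALSE],
    morphology = ((seq_len(n) - 1L) %% length(config$morphologies)) + 1L,
    camera_seed = sample.int(.Machine$integer.max, n),
    appearance_seed = sample.int(.Machine$integer.max, n),
    background = ((seq_len(n) - 1L) %% n_bg) + 1L,
    row.names = NULL, stringsAsFactors = FALSE)
  class(plan) <- c("permutation_plan", class(plan))
  plan
}

# Seeded per-vertex appearance: skin tone on the limbs and head with mild
# jitter, a random clothing color on the torso/pelvis.
randomize_appearance <- function(mesh, assignment, seed) {
  set.seed(seed)
  skin <- pmin(1, pmax(0, c(0.87, 0.67, 0.53) * stats::runif(1, 0.7, 1.15)))
  cloth <- stats::runif(3, 0.05, 0.95)
  colors <- matrix(rep(skin, each = nrow(mesh$vertices)), ncol = 3)
  clothed <- grepl("torso|pelvis|femur", assignment)
  colors[clothed, ] <- matrix(rep(cloth, each = sum(clothed)), ncol = 3)
  jit <- stats::runif(nrow(mesh$vertices), 0.95, 1.05)
  colors <- colors * jit
  colors[] <- pmin(1, pmax(0, colors))
  colors
}

# Per-morphology rig cache: avatar mesh, armature, weights, vertex assignment
# and collision shapes, all built once in the rest pose.
build_rig <- function(model, morphology) {
  rest <- rest_transforms(model)
  mesh <- generate_avatar(model, morphology, rest)
  armature <- build_armature(model, rest)
  weights <- compute_weights(mesh, armature)
  assignment <- assign_vertices(weights, armature)
  shapes <- build_collision_shapes(mesh, assignment, rest)
  list(rest = rest, mesh = mesh, armature = armature, weights = weights,
       assignment = assignment, shapes = shapes)
}

#' Generate a dataset of annotated synthetic images
#'
#' Executes a permutation plan: for each planned image, poses the avatar,
#' samples a camera, renders the RGB image (`images/`), the whole-body
#' silhouette (`silhouettes/`) and one mask per modelled body segment
#' (`segments/<id>_<body>.png`), and collects the frame annotation. Finally
#' writes `annotations/annotations.csv` and `annotations/metadata.csv`.
#' Deterministic: the same config and seed reproduce byte-identical CSVs and
#' pixel-identical images before JPEG encoding.
#'
#' @param config a [dataset_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a manifest list with the plan, the annotation records
#'   and the file paths written.
#' @export
generate_dataset <- function(config, quiet = FALSE) {
  plan <- plan_permutations(config)
  dirs <- file.path(config$output_dir, c("images", "silhouettes", "segments", "annotations"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  model <- config$model
  trials <- if (config$subset == "real") resolve_motion(config) else NULL
  if (!is.null(trials)) names(trials) <- vapply(trials, `[[`, "", "name")
  rigs <- list()
  records <- vector("list", nrow(plan))
  meta <- vector("list", nrow(plan))
  bodies <- body_names(model)
  ext <- if (config$settings$rgb_format == "jpeg") "jpg" else "png"

  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    mi <- row$morphology
    if (is.null(rigs[[as.character(mi)]]))
      rigs[[as.character(mi)]] <- build_rig(model, config$morphologies[[mi]])
    rig <- rigs[[as.character(mi)]]

    pose <- if (config$subset == "real") {
      pose_from_frame(model, trials[[row$trial]], row$frame)
    } else {
      set.seed(row$pose_seed)
      random_pose(model)
    }
    transforms <- forward_kinematics(model, pose)
    skin <- skinning_transforms(rig$armature, transforms)
    deformed <- deform_mesh(rig$mesh, rig$weights, skin)

    set.seed(row$camera_seed)
    cam <- sample_camera(colMeans(deformed$vertices), config$cam_ranges)

    rgb_path <- file.path(dirs[1], sprintf("%s.%s", row$image_id, ext))
    sil_path <- file.path(dirs[2], sprintf("%s.png", row$image_id))
    seg_paths <- file.path(dirs[3], sprintf("%s_%s.png", row$image_id, bodies))
    exists_all <- all(file.exists(c(rgb_path, sil_path, seg_paths)))
    if (!(config$resume && exists_all)) {
      settings <- config$settings
      if (!is.null(config$backgrounds))
        settings$background <- config$backgrounds[[row$background]]
      colors <- randomize_appearance(rig$mesh, rig$assignment, row$appearance_seed)
      write_image(render_rgb(deformed, cam, settings, colors), rgb_path)
      write_image(render_silhouette(deformed, cam, settings), sil_path)
      for (k in seq_along(bodies))
        write_image(render_segment_mask(deformed, rig$weights, bodies[k], cam,
                                        settings, rig$armature), seg_paths[k])
    } else if (!quiet) {
      message(sprintf("[%s] images exist, skipping render", row$image_id))
    }

    records[[i]] <- annotate_frame(model, pose, deformed, cam, rig$shapes,
                                   transforms, step = config$step,
                                   padding = config$padding,
                                   image_id = row$image_id)
    morph <- config$morphologies[[mi]]
    meta[[i]] <- data.frame(
      image_id = row$image_id, subset = config$subset,
      pose_source = if (config$subset == "real")
        sprintf("%s:%d", row$trial, row$frame) else sprintf("random:%d", row$pose_seed),
      sex_tag = morph$sex_tag, shape = morph$shape,
      cam_x = cam$position[1], cam_y = cam$position[2], cam_z = cam$position[3],
      cam_fov = cam$fov, width = config$settings$width, height = config$settings$height,
      background = row$background, camera_seed = row$camera_seed,
      appearance_seed = row$appearance_seed, stringsAsFactors = FALSE)
    if (!quiet && (i == nrow(plan) || i %% 10 == 0))
      message(sprintf("rendered %d / %d images", i, nrow(plan)))
  }

  ann_path <- file.path(dirs[4], "annotations.csv")
  meta_path <- file.path(dirs[4], "metadata.csv")
  write_annotations_csv(records, ann_path)
  write_metadata_csv(do.call(rbind, meta), meta_path)
  invisible(list(plan = plan, records = records,
                 annotations = ann_path, metadata = meta_path,
                 output_dir = config$output_dir))
}

fmt6 <- function(x) {
  # 6 significant digits, "." decimal, no scientific notation surprises
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

#' Write frame annotations as a wide CSV
#'
#' One row per image: `image_id`, the bounding box (`bbox_x`, `bbox_y`,
#' `bbox_w`, `bbox_h`), then per keypoint K the quadruple `K_u`, `K_v`,
#' `K_depth`, `K_visibility` (keypoint order fixed by the model definition),
#' then one column per generalized coordinate. Values are written with 6
#' significant digits, "." decimal, UTF-8; the first line is a
#' `# schema_version` comment.
#'
#' @param records list of `frame_annotation` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(records, path) {
  if (length(records) == 0) stop("no records")
  kp0 <- records[[1]]$keypoints$name
  co0 <- names(records[[1]]$kinematics)
  rows <- lapply(records, function(r) {
    if (!identical(r$keypoints$name, kp0) || !identical(names(r$kinematics), co0))
      stop("inconsistent keypoint or coordinate sets across records")
    kp <- r$keypoints
    vals <- as.numeric(t(as.matrix(kp[, c("u", "v", "depth", "visibility")])))
    c(r$image_id,
      fmt6(c(r$bbox$x, r$bbox$y, r$bbox$width, r$bbox$height)),
      fmt6(vals), fmt6(unname(r$kinematics)))
  })
  header <- c("image_id", "bbox_x", "bbox_y", "bbox_w", "bbox_h",
              as.vector(t(outer(kp0, c("u", "v", "depth", "visibility"),
                                paste, sep = "_"))),
              co0)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# schema_version 1", con)
  writeLines(paste(header, collapse = ","), con)
  writeLines(vapply(rows, paste, "", collapse = ","), con)
  invisible(path)
}

#' Write per-image metadata as CSV
#'
#' One row per image: subset tag, pose source, morphology, camera position and
#' FOV, resolution, background index and the per-image seeds.
#'
#' @param meta data.frame assembled by [generate_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata_csv <- function(meta, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# schema_version 1", con)
  num <- vapply(meta, is.numeric, NA) & !vapply(meta, is.integer, NA)
  out <- meta
  for (j in which(num)) out[[j]] <- fmt6(meta[[j]])
  writeLines(paste(names(out), collapse = ","), con)
  writeLines(apply(out, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read back an annotations or metadata CSV
#' @param path CSV path written by this package.
#' @return data.frame.
#' @export
read_annotations_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = c(image_id = "character"))
}
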