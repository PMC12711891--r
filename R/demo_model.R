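#' Bundled demonstration skeletal model
#'
#' A 14-body full-body model echoing the segment list of classic full-body gait
#' models: pelvis, torso (including the head), and three segments per limb
#' (thigh/shank/foot, upper arm/forearm/hand). It has 29 bounded generalized
#' coordinates: a 6-DOF pelvis-to-ground joint, a 3-DOF lumbar joint, 3-DOF
#' hips and shoulders, and 1-DOF knees, ankles, elbows and wrists. The rest
#' pose (all coordinates at their defaults of zero) is a standing T-pose with
#' the arms horizontal, which is the reference pose for mesh generation and
#' rigging. Dimensions are average-adult segment lengths in meters; ranges are
#' plausible anatomical ranges in radians (translations in meters).
#'
#' @return a validated `skeletal_model`.
#' @export
demo_model <- function() {
  deg <- pi / 180

  co <- function(name, lo, hi, default = 0) {
    list(name = name, range_min = lo, range_max = hi, default = default)
  }
  dof_rot <- function(coordinate, axis) list(coordinate = coordinate, kind = "rotation", axis = axis)
  dof_tra <- function(coordinate, axis) list(coordinate = coordinate, kind = "translation", axis = axis)
  X <- c(1, 0, 0); Y <- c(0, 1, 0); Z <- c(0, 0, 1)

  bodies <- list(
    list(name = "pelvis"),
    list(name = "torso"),
    list(name = "femur_r"), list(name = "tibia_r"),
    list(name = "foot_r", leaf_direction = unit(c(0, -0.25, 1))),
    list(name = "femur_l"), list(name = "tibia_l"),
    list(name = "foot_l", leaf_direction = unit(c(0, -0.25, 1))),
    list(name = "humerus_r"), list(name = "ulna_r"),
    list(name = "hand_r", leaf_direction = X),
    list(name = "humerus_l"), list(name = "ulna_l"),
    list(name = "hand_l", leaf_direction = -X))

  coordinates <- list(
    co("pelvis_tilt", -90 * deg, 90 * deg),
    co("pelvis_list", -90 * deg, 90 * deg),
    co("pelvis_rotation", -pi, pi),
    co("pelvis_tx", -5, 5), co("pelvis_ty", -1, 2), co("pelvis_tz", -5, 5),
    co("lumbar_extension", -60 * deg, 30 * deg),
    co("lumbar_bending", -35 * deg, 35 * deg),
    co("lumbar_rotation", -40 * deg, 40 * deg),
    co("hip_flexion_r", -30 * deg, 120 * deg), co("hip_adduction_r", -50 * deg, 30 * deg),
    co("hip_rotation_r", -40 * deg, 40 * deg), co("knee_angle_r", -120 * deg, 10 * deg),
    co("ankle_angle_r", -50 * deg, 30 * deg),
    co("hip_flexion_l", -30 * deg, 120 * deg), co("hip_adduction_l", -50 * deg, 30 * deg),
    co("hip_rotation_l", -40 * deg, 40 * deg), co("knee_angle_l", -120 * deg, 10 * deg),
    co("ankle_angle_l", -50 * deg, 30 * deg),
    co("arm_flex_r", -90 * deg, 180 * deg), co("arm_add_r", -120 * deg, 60 * deg),
    co("arm_rot_r", -90 * deg, 90 * deg), co("elbow_flex_r", 0, 150 * deg),
    co("wrist_flex_r", -70 * deg, 70 * deg),
    co("arm_flex_l", -90 * deg, 180 * deg), co("arm_add_l", -120 * deg, 60 * deg),
    co("arm_rot_l", -90 * deg, 90 * deg), co("elbow_flex_l", 0, 150 * deg),
    co("wrist_flex_l", -70 * deg, 70 * deg))

  # Side-mirrored joint locations: right-side x > 0, left-side x < 0.
  joints <- list(
    list(name = "ground_pelvis", parent_body = "ground", child_body = "pelvis",
         location_in_parent = c(0, 0.95, 0), location_in_child = c(0, 0, 0),
         dofs = list(dof_rot("pelvis_tilt", X), dof_rot("pelvis_list", Z),
                     dof_rot("pelvis_rotation", Y),
                     dof_tra("pelvis_tx", X), dof_tra("pelvis_ty", Y), dof_tra("pelvis_tz", Z))),
    list(name = "lumbar", parent_body = "pelvis", child_body = "torso",
         location_in_parent = c(0, 0.10, 0), location_in_child = c(0, 0, 0),
         dofs = list(dof_rot("lumbar_extension", X), dof_rot("lumbar_bending", Z),
                     dof_rot("lumbar_rotation", Y))),
    list(name = "hip_r", parent_body = "pelvis", child_body = "femur_r",
         location_in_parent = c(0.09, -0.07, 0), location_in_child = c(0, 0, 0),
         dofs = list(dof_rot("hip_flexion_r", X), dof_rot("hip_adduction_r", Z),
                     dof_rot("hip_rotation_r", Y))),
    list(name = "knee_r", parent_body = "femur_r", child_body = "tibia_r",
         location_in_parent = c(0, -0.42, 0), location_in_child = c(0, 0, 0),
         dofs = list(dof_rot("knee_angle_r", X))),
    list(name = "ankle_r", parent_body = "tibia_r", child_body = "foot_r",
         location_in_parent = c(0, -0.43, 0), location_in_child = c(0, 0, 0),
         dofs = list(dof_rot("ankle_angle_r", X))),
    list(name = "hip_l", parent_body = "pelvis", child_body = "femur_l",
         location_in_parent = c(-0.09, -0.07, 0), location_in_child = c(0, 0, 0),
         dofs = list(dof_rot("hip_flexion_l", X), dof_rot("hip_adduction_l", Z),
                     dof_rot("hip_rotation_l", Y))),
    list(name = "knee_l", parent_body = "femur_l", child_body = "tibia_l",
         location_in_parent = c(0, -0.42, 0), location_in_child = c(0, 0, 0),
         dofs = list(dof_rot("knee_angle_l", X))),
    list(name = "ankle_l", parent_body = "tibia_l", child_body = "foot_l",
         location_in_parent = c(0, -0.43, 0), location_in_child = c(0, 0, 0),
         dofs = list(dof_rot("ankle_angle_l", X))),
    list(name = "shoulder_r", parent_body = "torso", child_body = "humerus_r",
         location_in_parent = c(0.18, 0.42, 0), location_in_child = c(0, 0, 0),
         dofs = list(dof_rot("arm_flex_r", X), dof_rot("arm_add_r", Z),
                     dof_rot("arm_rot_r", Y))),
    list(name = "elbow_r", parent_body = "humerus_r", child_body = "ulna_r",
         location_in_parent = c(0.28, 0, 0), location_in_child = c(0, 0, 0),
         dofs = list(dof_rot("elbow_flex_r", Y))),
    list(name = "wrist_r", parent_body = "ulna_r", child_body = "hand_r",
         location_in_parent = c(0.26, 0, 0), location_in_child = c(0, 0, 0),
         dofs = list(dof_rot("wrist_flex_r", Z))),
    list(name = "shoulder_l", parent_body = "torso", child_body = "humerus_l",
         location_in_parent = c(-0.18, 0.42, 0), location_in_child = c(0, 0, 0),
         dofs = list(dof_rot("arm_flex_l", X), dof_rot("arm_add_l", Z),
                     dof_rot("arm_rot_l", Y))),
    list(name = "elbow_l", parent_body = "humerus_l", child_body = "ulna_l",
         location_in_parent = c(-0.28, 0, 0), location_in_child = c(0, 0, 0),
         dofs = list(dof_rot("elbow_flex_l", Y))),
    list(name = "wrist_l", parent_body = "ulna_l", child_body = "hand_l",
         location_in_parent = c(-0.26, 0, 0), location_in_child = c(0, 0, 0),
         dofs = list(dof_rot("wrist_flex_l", Z))))

  markers <- list(
    list(name = "RASI", body = "pelvis", offset = c(0.11, 0.02, 0.08)),
    list(name = "LASI", body = "pelvis", offset = c(-0.11, 0.02, 0.08)),
    list(name = "C7", body = "torso", offset = c(0, 0.40, -0.06)),
    list(name = "STRN", body = "torso", offset = c(0, 0.25, 0.10)),
    list(name = "RKNE", body = "femur_r", offset = c(0.06, -0.42, 0)),
    list(name = "LKNE", body = "femur_l", offset = c(-0.06, -0.42, 0)),
    list(name = "RANK", body = "tibia_r", offset = c(0.05, -0.43, 0)),
    list(name = "LANK", body = "tibia_l", offset = c(-0.05, -0.43, 0)),
    list(name = "RWRA", body = "ulna_r", offset = c(0.26, 0.03, 0)),
    list(name = "LWRA", body = "ulna_l", offset = c(-0.26, 0.03, 0)))

  skeletal_model(name = "skelsynth_demo", bodies = bodies, joints = joints,
                 coordinates = coordinates, markers = markers)
}
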