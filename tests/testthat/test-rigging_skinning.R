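test_that("armature follows the segment/control/connector construction rules", {
  m <- demo_model()
  rest <- rest_transforms(m)
  arm <- build_armature(m, rest)
  centers <- joint_centers(m, rest, check = FALSE)
  # femur segment bone spans hip -> knee
  fem <- arm$bones[["seg_femur_r"]]
  expect_equal(fem$head, centers$hip_r, tolerance = 1e-12)
  expect_equal(fem$tail, centers$knee_r, tolerance = 1e-12)
  # branching torso: tail at midpoint of the two shoulder joint centers
  tor <- arm$bones[["seg_torso"]]
  expect_equal(tor$tail, (centers$shoulder_r + centers$shoulder_l) / 2,
               tolerance = 1e-12)
  # leaf hand continues for the fixed distance along its leaf direction
  hand <- arm$bones[["seg_hand_r"]]
  expect_equal(vnorm(hand$tail - hand$head), 0.12, tolerance = 1e-12)
  # control bones: fixed length, shared head, body rest rotation
  for (b in body_names(m)) {
    cb <- arm$bones[[arm$body_to_control[[b]]]]
    sb <- arm$bones[[arm$body_to_segment[[b]]]]
    expect_equal(cb$head, sb$head)
    expect_equal(vnorm(cb$tail - cb$head), 0.10, tolerance = 1e-12)
    expect_equal(cb$rest_rotation, rest[[b]]$R)
    expect_identical(sb$parent, cb$name)
  }
  # torso tail (mid-shoulders) != humerus head (shoulder): connector exists
  conn <- Filter(function(b) b$kind == "connector", arm$bones)
  nms <- vapply(conn, `[[`, "", "name")
  expect_true("conn_torso_humerus_r" %in% nms)
  cb <- arm$bones[["conn_torso_humerus_r"]]
  expect_equal(cb$head, tor$tail)
  expect_equal(cb$tail, centers$shoulder_r)
  expect_identical(cb$origin_segment, "seg_torso")
  # connected connectors attach to their parent's tail
  expect_true(cb$connected)
})

test_that("weights: nearest-bone dominance, symmetry and normalization", {
  arm <- make_armature(list(
    a = list(head = c(0, 0, 0), tail = c(0, 1, 0)),
    b = list(head = c(2, 0, 0), tail = c(2, 1, 0))))
  V <- rbind(c(0, 0.5, 0),     # on bone a's axis
             c(1, 0.5, 0),     # equidistant
             c(2, 0.5, 0))     # on bone b's axis
  mesh <- triangle_mesh(V, rbind(c(1, 2, 3)))
  W <- compute_weights(mesh, arm)
  expect_gt(W[1, "seg_a"], 0.99)
  expect_equal(unname(W[2, ]), c(0.5, 0.5), tolerance = 1e-9)
  expect_gt(W[3, "seg_b"], 0.99)
  expect_equal(rowSums(W), rep(1, 3), tolerance = 1e-9)
  expect_true(all(W >= 0))
})

test_that("connector weights transfer to the originating segment bone", {
  arm <- make_armature(list(
    a = list(head = c(0, 0, 0), tail = c(0, 1, 0)),
    b = list(head = c(0, 2, 0), tail = c(0, 3, 0))))
  # add a connector from a's tail to b's head
  arm$bones[["conn_a_b"]] <- list(name = "conn_a_b", kind = "connector",
                                  head = c(0, 1, 0), tail = c(0, 2, 0),
                                  parent = "seg_a", connected = TRUE,
                                  rest_rotation = diag(3),
                                  origin_segment = "seg_a")
  V <- rbind(c(0.05, 1.5, 0),  # sits on the connector span
             c(0, 0.5, 0), c(0, 2.5, 0))
  mesh <- triangle_mesh(V, rbind(c(1, 2, 3)))
  W <- compute_weights(mesh, arm)
  # total mass conserved: rows still sum to one over segment bones only
  expect_equal(rowSums(W), rep(1, 3), tolerance = 1e-9)
  expect_equal(colnames(W), c("seg_a", "seg_b"))
  # the connector-span vertex is dominated by seg_a (origin of the connector),
  # even though seg_a and seg_b are geometrically equidistant from it
  expect_gt(W[1, "seg_a"], W[1, "seg_b"])
})

test_that("skinning transforms equal the body transform change (control-bone rule)", {
  m <- demo_model()
  rest <- rest_transforms(m)
  arm <- build_armature(m, rest)
  set.seed(42)
  for (rep in 1:5) {
    pose <- random_pose(m)
    tf <- forward_kinematics(m, pose)
    S <- skinning_transforms(arm, tf)
    for (b in body_names(m)) {
      # independent oracle: direct rigid-transform product
      oracle_R <- tf[[b]]$R %*% t(rest[[b]]$R)
      oracle_t <- tf[[b]]$t - oracle_R %*% rest[[b]]$t
      Sb <- S[[arm$body_to_segment[[b]]]]
      expect_lt(max(abs(Sb$R - oracle_R)), 1e-9)
      expect_lt(max(abs(Sb$t - as.numeric(oracle_t))), 1e-9)
    }
  }
  # rest pose: identity skinning transforms
  S0 <- skinning_transforms(arm, rest)
  for (s in S0) {
    expect_equal(s$R, diag(3), tolerance = 1e-9)
    expect_equal(s$t, c(0, 0, 0), tolerance = 1e-9)
  }
})

test_that("linear blend skinning: identity, rigid-weight and common-motion cases", {
  m <- demo_model()
  av <- generate_avatar(m, morphology_params(mesh_resolution = 1000))
  arm <- build_armature(m)
  W <- compute_weights(av, arm)
  # identity transforms reproduce the mesh
  id <- lapply(colnames(W), function(x) list(R = diag(3), t = c(0, 0, 0)))
  names(id) <- colnames(W)
  expect_equal(deform_mesh(av, W, id)$vertices, av$vertices, tolerance = 1e-12)
  # all bones sharing one rigid transform move the whole mesh rigidly
  Tcommon <- list(R = skelsynth:::rot_axis_angle(c(0, 1, 0), 0.7), t = c(0.3, -0.2, 1))
  common <- lapply(colnames(W), function(x) Tcommon)
  names(common) <- colnames(W)
  got <- deform_mesh(av, W, common)$vertices
  oracle <- sweep(av$vertices %*% t(Tcommon$R), 2, Tcommon$t, "+")
  expect_lt(max(abs(got - oracle)), 1e-9)
  # a weight-1 vertex moves rigidly with its bone
  Wr <- matrix(0, 2, ncol(W), dimnames = list(NULL, colnames(W)))
  Wr[, 2] <- 1
  class(Wr) <- c("weight_matrix", class(Wr))
  mesh2 <- triangle_mesh(rbind(c(0.1, 0.2, 0.3), c(0, 0, 1)), matrix(0, 0, 3))
  skin <- id; skin[[2]] <- Tcommon
  d2 <- deform_mesh(mesh2, Wr, skin)
  expect_equal(d2$vertices[1, ],
               as.numeric(Tcommon$R %*% c(0.1, 0.2, 0.3) + Tcommon$t),
               tolerance = 1e-12)
  expect_error(deform_mesh(av, W[1:5, ], id), "match")
})

test_that("vertex assignment takes the argmax with low-index ties", {
  W <- rbind(c(0.7, 0.3), c(0.5, 0.5), c(0.2, 0.8))
  colnames(W) <- c("seg_a", "seg_b")
  expect_equal(assign_vertices(W), c("seg_a", "seg_a", "seg_b"))
  # every demo segment attracts at least one vertex
  m <- demo_model()
  av <- generate_avatar(m, morphology_params(mesh_resolution = 3000))
  arm <- build_armature(m)
  asg <- assign_vertices(compute_weights(av, arm), arm)
  expect_setequal(unique(asg), body_names(m))
})

test_that("armature serializes to JSON", {
  arm <- build_armature(toy_chain_model(2))
  path <- withr::local_tempfile(fileext = ".json")
  write_armature_json(arm, path)
  back <- jsonlite::read_json(path)
  expect_equal(length(back$bones), length(arm$bones))
})
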