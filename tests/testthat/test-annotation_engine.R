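test_that("convex hull: cube, containment of inputs, volume, degeneracy", {
  cube <- box_corners(half = c(0.5, 0.5, 0.5))
  h <- convex_hull_3d(cube)
  expect_false(h$degenerate)
  expect_length(h$vertices, 8)
  expect_equal(hull_volume(h, cube), 1, tolerance = 1e-9)
  expect_true(all(point_in_hull(h, cube, tol = 1e-9)))
  expect_false(point_in_hull(h, c(0.6, 0, 0)))
  # random clouds: every input point inside its own hull
  set.seed(3)
  for (rep in 1:10) {
    P <- matrix(rnorm(3 * 40), ncol = 3)
    hp <- convex_hull_3d(P)
    expect_true(all(point_in_hull(hp, P, tol = 1e-7)))
    expect_true(all(hp$vertices %in% seq_len(40)))
  }
  # a concave crescent of points yields its convex closure
  theta <- seq(0, pi, length.out = 30)
  crescent <- rbind(cbind(cos(theta), sin(theta), 0),
                    cbind(cos(theta), sin(theta), 0.3))
  hc <- convex_hull_3d(crescent)
  expect_true(point_in_hull(hc, c(0, 0.5, 0.15)))  # concavity is filled
  # coplanar points are degenerate
  expect_true(convex_hull_3d(cbind(rnorm(10), rnorm(10), 0))$degenerate)
  expect_true(convex_hull_3d(matrix(rnorm(9), 3, 3))$degenerate)
})

test_that("bbox_3d: stride semantics and containment in the full box", {
  cube <- triangle_mesh(box_corners(half = c(0.5, 0.5, 0.5)), rbind(c(1, 2, 3)))
  c1 <- bbox_3d(cube, step = 1)
  expect_equal(apply(c1, 2, max) - apply(c1, 2, min), c(x = 1, y = 1, z = 1))
  # 8-vertex mesh, step 25: only vertex 1 sampled -> degenerate box there
  c25 <- bbox_3d(cube, step = 25)
  expect_true(all(apply(c25, 2, function(x) diff(range(x))) == 0))
  expect_equal(unname(c25[1, ]), unname(cube$vertices[1, ]))
  # avatar: subsampled box contained in the full box on every axis
  av <- generate_avatar(demo_model())
  f <- bbox_3d(av, step = 1); s <- bbox_3d(av, step = 5)
  expect_true(all(apply(s, 2, min) >= apply(f, 2, min) - 1e-12))
  expect_true(all(apply(s, 2, max) <= apply(f, 2, max) + 1e-12))
  expect_error(bbox_3d(av, step = 0), "step")
})

test_that("bbox_2d: padding arithmetic and corner containment", {
  cam <- camera(c(0, 0, 0), c(0, 0, 1), fov = 60)
  # face-on box at depth 4 with half-width 0.5: projected half-width r
  corners <- skelsynth:::rt_apply(skelsynth:::rt_translate(c(0, 0, 4)),
                                  box_corners(half = c(0.5, 0.5, 0.001)))
  r1 <- cam$focal * 0.5 / 3.999  # the near face dominates the projection
  bb <- bbox_2d(cam, corners, padding = 25)
  expect_equal(bb$width, 2 * r1 + 50, tolerance = 1e-9)
  bb0 <- bbox_2d(cam, corners, padding = 0)
  expect_equal(bb$width, bb0$width + 50)
  expect_equal(bb$height, bb0$height + 50)
  expect_equal(bb$x, bb0$x - 25)
  expect_equal(bb$y, bb0$y - 25)
  # random box poses: all projected corners inside the padded box
  set.seed(9)
  for (rep in 1:20) {
    R <- rand_rot()
    corners <- sweep(box_corners(half = runif(3, 0.1, 0.6)) %*% t(R),
                     2, c(runif(1, -1, 1), runif(1, -1, 1), runif(1, 3, 8)), "+")
    bb <- bbox_2d(cam, corners, padding = 25)
    pr <- project(cam, corners)
    expect_true(all(pr$u >= bb$x & pr$u <= bb$x + bb$width &
                      pr$v >= bb$y & pr$v <= bb$y + bb$height))
  }
  behind <- sweep(box_corners(), 2, c(0, 0, -5), "+")
  expect_error(bbox_2d(cam, behind), class = "skelsynth_bbox_error")
})

test_that("collision shapes are built per segment in body-local frames", {
  m <- demo_model()
  rest <- rest_transforms(m)
  av <- generate_avatar(m)
  arm <- build_armature(m, rest)
  asg <- assign_vertices(compute_weights(av, arm), arm)
  shapes <- build_collision_shapes(av, asg, rest)
  expect_s3_class(shapes, "collision_shape_set")
  expect_setequal(names(shapes), body_names(m))
  expect_true(all(!vapply(shapes, function(s) isTRUE(s$hull$degenerate), NA)))
  # shapes are frame-invariant: rebuilt shapes are identical (built once)
  shapes2 <- build_collision_shapes(av, asg, rest)
  expect_identical(shapes, shapes2)
  # cube segment: hull has 8 vertices
  cube <- triangle_mesh(box_corners(), rbind(c(1, 2, 3)))
  sh <- build_collision_shapes(cube, rep("pelvis", 8),
                               list(pelvis = list(R = diag(3), t = c(0, 0, 0))))
  expect_length(sh$pelvis$hull$vertices, 8)
  expect_error(build_collision_shapes(cube, rep("pelvis", 3), rest), "cover")
})

test_that("collider counting: trivial cases and the hip-in-segment example", {
  tf <- identity_transforms("b1")
  # empty shape set
  empty <- structure(list(), class = "collision_shape_set")
  expect_equal(count_colliders(c(0, 0, -5), c(0, 0, 0), empty, tf), 0L)
  # landmark at the centroid of a single hull, camera outside: N = 1
  shapes <- make_shapes(list(b1 = box_corners()))
  expect_equal(count_colliders(c(0, 0, -5), c(0, 0, 0), shapes, tf), 1L)
  expect_equal(visibility(count_colliders(c(0, 0, -5), c(0, 0, 0), shapes, tf)), 0.5)
  # camera inside the hull also counts (entered at distance 0)
  expect_equal(count_colliders(c(0, 0, 0.2), c(0, 0, 0), shapes, tf), 1L)
  # shape entirely behind the landmark does not count
  behind <- make_shapes(list(b1 = sweep(box_corners(), 2, c(0, 0, 5), "+")))
  expect_equal(count_colliders(c(0, 0, -5), c(0, 0, 0), behind, tf), 0L)
  # two disjoint cubes straddling the ray: N = 2, against the dense oracle
  two <- make_shapes(list(b1 = sweep(box_corners(half = rep(0.4, 3)), 2, c(0, 0, -3), "+"),
                          b2 = sweep(box_corners(half = rep(0.4, 3)), 2, c(0, 0, -1.5), "+")))
  tf2 <- identity_transforms(c("b1", "b2"))
  expect_equal(count_colliders(c(0, 0, -5), c(0, 0, 0), two, tf2), 2L)
  boxes <- list(list(center = c(0, 0, -3), half = rep(0.4, 3), R = diag(3)),
                list(center = c(0, 0, -1.5), half = rep(0.4, 3), R = diag(3)))
  expect_equal(oracle_count(c(0, 0, -5), c(0, 0, 0), boxes, n_samples = 10000), 2)
})

test_that("collider counting agrees with the dense-sampling oracle on random scenes", {
  set.seed(1234)
  n_scenes <- 200
  for (scene in seq_len(n_scenes)) {
    k <- sample(1:4, 1)
    boxes <- lapply(seq_len(k), function(i)
      list(center = runif(3, -1.5, 1.5), half = runif(3, 0.25, 0.7),
           R = rand_rot()))
    # shapes as world point clouds with body transforms carrying the placement
    tfs <- lapply(boxes, function(b) list(R = b$R, t = b$center))
    names(tfs) <- sprintf("b%d", seq_len(k))
    class(tfs) <- "body_transforms"
    shapes <- lapply(seq_len(k), function(i)
      list(body = sprintf("b%d", i),
           hull = convex_hull_3d(box_corners(half = boxes[[i]]$half)),
           points = NULL))
    names(shapes) <- names(tfs)
    class(shapes) <- "collision_shape_set"
    origin <- unit(rnorm(3)) * 6
    landmark <- runif(3, -1, 1)
    got <- count_colliders(origin, landmark, shapes, tfs)
    want <- oracle_count(origin, landmark, boxes)
    expect_equal(got, want,
                 info = sprintf("scene %d", scene))
  }
})

test_that("visibility formula: exact endpoints, range and monotonicity", {
  expect_identical(visibility(0), 1)
  expect_equal(visibility(1), 0.5)
  expect_equal(visibility(3), 0.25)
  v <- visibility(0:100)
  expect_true(all(v > 0 & v <= 1))
  expect_true(all(diff(v) < 0))
  expect_error(visibility(-1), "non-negative")
})

test_that("annotate_frame produces the complete, deterministic record", {
  m <- demo_model()
  rest <- rest_transforms(m)
  av <- generate_avatar(m, morphology_params(mesh_resolution = 2000))
  arm <- build_armature(m, rest)
  W <- compute_weights(av, arm)
  asg <- assign_vertices(W, arm)
  shapes <- build_collision_shapes(av, asg, rest)
  set.seed(55)
  pose <- random_pose(m)
  tf <- forward_kinematics(m, pose)
  d <- deform_mesh(av, W, skinning_transforms(arm, tf))
  cam <- sample_camera(colMeans(d$vertices))
  ann <- annotate_frame(m, pose, d, cam, shapes, tf)
  expect_equal(nrow(ann$keypoints),
               length(m$joints) + length(m$bodies) + length(m$markers))
  expect_false(anyDuplicated(ann$keypoints$name) > 0)
  expect_true(all(ann$keypoints$visibility > 0 & ann$keypoints$visibility <= 1))
  expect_true(all(ann$keypoints$depth >= 0))
  expect_equal(names(ann$kinematics), coordinate_names(m))
  # joint and body keypoints coincide where the body origin sits at its joint
  kp <- ann$keypoints
  for (pair in list(c("joint_hip_r", "body_femur_r"), c("joint_lumbar", "body_torso"))) {
    a <- kp[kp$name == pair[1], ]; b <- kp[kp$name == pair[2], ]
    expect_equal(c(a$u, a$v), c(b$u, b$v), tolerance = 1e-9)
  }
  ann2 <- annotate_frame(m, pose, d, cam, shapes, tf)
  expect_identical(ann, ann2)
})
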