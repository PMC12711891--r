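test_that("model construction, save/load round-trip and field counts", {
  m <- toy_hinge_model()
  expect_s3_class(m, "skeletal_model")
  expect_length(m$bodies, 2)
  expect_length(m$joints, 2)
  expect_length(m$coordinates, 1)

  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$bodies, m$bodies)
  expect_equal(m2$joints, m$joints)
  expect_equal(m2$coordinates, m$coordinates)
  expect_equal(m2$markers, m$markers)
})

test_that("invalid topology and bad fields are rejected with typed errors", {
  m <- toy_hinge_model()
  bad <- unclass(m)
  bad$joints[[2]]$child_body <- "nonexistent"
  expect_error(skeletal_model(bad$name, bad$bodies, bad$joints, bad$coordinates),
               class = "skelsynth_topology_error")
  # two roots
  bad2 <- unclass(m)
  bad2$joints[[2]]$parent_body <- "ground"
  expect_error(skeletal_model(bad2$name, bad2$bodies, bad2$joints, bad2$coordinates),
               class = "skelsynth_topology_error")
  # degenerate coordinate range
  expect_error(skeletal_model("x", m$bodies, m$joints,
                              list(co_("hip_angle", 1, 1))),
               class = "skelsynth_format_error")
  # non-unit axis
  bad3 <- unclass(m)
  bad3$joints[[2]]$dofs[[1]]$axis <- c(0, 0, 2)
  expect_error(skeletal_model(bad3$name, bad3$bodies, bad3$joints, bad3$coordinates),
               class = "skelsynth_format_error")
  expect_error(load_model(withr::local_tempfile(fileext = ".json")), "not found")
})

test_that("forward kinematics matches rest at zero and translates rigidly", {
  m <- toy_chain_model(3)
  p0 <- default_pose(m)
  tf0 <- forward_kinematics(m, p0)
  for (b in c("b1", "b2", "b3")) {
    expect_equal(tf0[[b]]$R, diag(3), tolerance = 1e-12)
  }
  expect_equal(tf0$b2$t, c(0, -0.5, 0))
  # pure root translation shifts every origin
  p <- p0; p[c("tx", "ty", "tz")] <- c(1, 2, 3)
  tf <- forward_kinematics(m, p)
  for (b in c("b1", "b2", "b3"))
    expect_equal(tf[[b]]$t, tf0[[b]]$t + c(1, 2, 3), tolerance = 1e-12)
  # missing coordinate
  expect_error(forward_kinematics(m, p0[-1]), class = "skelsynth_incomplete_pose")
})

test_that("FK equals the independent homogeneous-matrix oracle on chains", {
  for (n in 2:4) {
    m <- toy_chain_model(n)
    set.seed(100 + n)
    for (rep in 1:5) {
      pose <- random_pose(m, translation_policy = "sampled")
      tf <- forward_kinematics(m, pose)
      orc <- chain_oracle(pose, n)
      for (b in names(orc)) {
        expect_equal(tf[[b]]$R, orc[[b]][1:3, 1:3], tolerance = 1e-9)
        expect_equal(tf[[b]]$t, orc[[b]][1:3, 4], tolerance = 1e-9)
      }
    }
  }
  # hand-checked single hinge at 90 degrees about Z
  m <- toy_hinge_model(axis = c(0, 0, 1))
  tf <- forward_kinematics(m, c(hip_angle = pi / 2))
  expect_equal(tf$femur$R, matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3),
               tolerance = 1e-12)
  expect_equal(tf$femur$t, c(0, -0.1, 0), tolerance = 1e-12)
})

test_that("output rotations stay orthonormal with unit determinant", {
  m <- demo_model()
  set.seed(11)
  for (rep in 1:10) {
    tf <- forward_kinematics(m, random_pose(m, "sampled"))
    for (b in names(tf)) {
      R <- tf[[b]]$R
      expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
      expect_equal(det(R), 1, tolerance = 1e-9)
    }
  }
})

test_that("joint centers: parent and child side agree; chain oracle", {
  m <- demo_model()
  set.seed(21)
  for (rep in 1:5) {
    tf <- forward_kinematics(m, random_pose(m, "sampled"))
    expect_silent(joint_centers(m, tf, check = TRUE))  # internal 1e-9 check
  }
  # rest pose of a chain: centers at chained offsets
  mc <- toy_chain_model(3)
  tfc <- forward_kinematics(mc, default_pose(mc))
  jc <- joint_centers(mc, tfc)
  expect_equal(jc$root, c(0, 0, 0))
  expect_equal(jc$j2, c(0, -0.5, 0))
  expect_equal(jc$j3, c(0, -1.0, 0))
  # posed chain vs oracle (joint i center = oracle transform of b_{i-1} at lip)
  set.seed(22)
  pose <- random_pose(mc, "sampled")
  tfp <- forward_kinematics(mc, pose)
  orc <- chain_oracle(pose, 3)
  jcp <- joint_centers(mc, tfp)
  expect_equal(jcp$j2, H_apply(orc$b1, c(0, -0.5, 0)), tolerance = 1e-9)
  expect_equal(jcp$j3, H_apply(orc$b2, c(0, -0.5, 0)), tolerance = 1e-9)
})

test_that("marker positions follow body frames", {
  m <- toy_hinge_model(axis = c(0, 1, 0))  # hinge about Y
  tf0 <- forward_kinematics(m, c(hip_angle = 0))
  mk0 <- marker_positions(m, tf0)
  expect_equal(mk0$M1, c(0.1, -0.1, 0))
  # body rotated 180 deg about Y: x-offset flips
  tf <- forward_kinematics(m, c(hip_angle = pi))
  mk <- marker_positions(m, tf)
  expect_equal(mk$M1 - tf$femur$t, c(-0.1, 0, 0), tolerance = 1e-12)
  # random pose vs direct transform application
  m2 <- toy_chain_model(3)
  m2$markers <- list(list(name = "MM", body = "b3", offset = c(0.2, -0.1, 0.05)))
  set.seed(31)
  pose <- random_pose(m2, "sampled")
  tfp <- forward_kinematics(m2, pose)
  orc <- chain_oracle(pose, 3)
  expect_equal(marker_positions(m2, tfp)$MM,
               H_apply(orc$b3, c(0.2, -0.1, 0.05)), tolerance = 1e-9)
})

test_that("random poses respect ranges, determinism and uniformity", {
  m <- toy_hinge_model(lo = -1, hi = 1)
  set.seed(5)
  draws <- replicate(10000, random_pose(m)[["hip_angle"]])
  expect_true(all(draws >= -1 & draws <= 1))
  ks <- unname(stats::ks.test(draws, "punif", -1, 1)$statistic)
  expect_lt(ks, 1.6276 / sqrt(10000))  # 1% critical value
  set.seed(99); a <- random_pose(demo_model(), "sampled")
  set.seed(99); b <- random_pose(demo_model(), "sampled")
  expect_identical(a, b)
  # fixed policy holds root translations at defaults
  set.seed(1)
  p <- random_pose(demo_model(), "fixed")
  expect_equal(unname(p[c("pelvis_tx", "pelvis_ty", "pelvis_tz")]), c(0, 0, 0))
  # out-of-range pose warns, strict rejects
  mh <- toy_hinge_model(lo = -1, hi = 1)
  expect_warning(forward_kinematics(mh, c(hip_angle = 2)), "out of")
  expect_error(suppressWarnings(forward_kinematics(mh, c(hip_angle = 2), strict = TRUE)))
})

test_that("FK is deterministic: identical inputs give identical transforms", {
  m <- demo_model()
  set.seed(77)
  p <- random_pose(m)
  expect_identical(forward_kinematics(m, p), forward_kinematics(m, p))
})
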