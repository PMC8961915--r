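test_that("relative pose of identical placements is the identity", {
  ff <- build_femoral_frame(aligned_femur_landmarks())
  tf <- build_tibial_frame(aligned_tibia_landmarks())
  p <- rigid_pose(rotvec_to_matrix(c(0.3, 0.1, -0.2)), c(10, -5, 3))
  T <- relative_pose(p, p, ff, ff)
  expect_pose_equal(T, rigid_pose())
})

test_that("relative pose is invariant to common rigid motions", {
  set.seed(7)
  ff <- build_femoral_frame(aligned_femur_landmarks())
  tf <- build_tibial_frame(aligned_tibia_landmarks())
  fp <- rigid_pose(rotvec_to_matrix(c(0.4, -0.3, 0.9)), c(20, 5, -12))
  tp <- rigid_pose(rotvec_to_matrix(c(-0.1, 0.2, 0.3)), c(-4, 9, 1))
  T0 <- relative_pose(fp, tp, ff, tf)
  for (i in 1:100) {
    G <- rigid_pose(random_rotation(), rnorm(3, 0, 100))
    T1 <- relative_pose(pose_compose(G, fp), pose_compose(G, tp), ff, tf)
    expect_pose_equal(T1, T0, tol = 1e-8)
  }
})

test_that("frames offset by a pure translation give zero rotation", {
  ff <- build_femoral_frame(aligned_femur_landmarks())
  d <- c(3, -7, 41)
  fp <- rigid_pose(diag(3), d)
  tp <- rigid_pose(diag(3), c(0, 0, 0))
  T <- relative_pose(fp, tp, ff, ff)
  expect_equal(T$R, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(T$t, d)
})

test_that("identity and single-axis joint states decompose trivially", {
  js0 <- decompose_jcs(rigid_pose())
  expect_equal(unlist(js0[1, ]), c(flexion = 0, varus = 0, external = 0,
                                   posterior = 0, medial = 0, superior = 0))
  # pure 90-degree flexion about the femoral X axis
  T <- compose_jcs(joint_state(flexion = 90))
  js <- decompose_jcs(T)
  expect_equal(js$flexion, 90)
  expect_equal(js$varus, 0)
  expect_equal(js$external, 0)
})

test_that("compose/decompose round-trips 1000 random states to 1e-9", {
  set.seed(123)
  worst <- 0
  for (i in 1:1000) {
    js <- random_joint_state()
    T <- compose_jcs(js)
    js2 <- decompose_jcs(T)
    e <- unlist(js2[1, ]) - unlist(js[1, ])
    e[c("flexion", "external")] <-
      (e[c("flexion", "external")] + 180) %% 360 - 180
    worst <- max(worst, max(abs(e)))
    # and the transform itself round-trips
    T2 <- compose_jcs(js2)
    worst <- max(worst, max(abs(T2$R - T$R)), max(abs(T2$t - T$t)))
  }
  expect_lt(worst, 1e-9)
})

test_that("tibial-axis translation mode is self-consistent too", {
  set.seed(5)
  for (i in 1:50) {
    js <- random_joint_state()
    T <- compose_jcs(js, translations = "tibial")
    js2 <- decompose_jcs(T, translations = "tibial")
    expect_equal(js2$posterior, js$posterior, tolerance = 1e-9)
    expect_equal(js2$medial, js$medial, tolerance = 1e-9)
    expect_equal(js2$superior, js$superior, tolerance = 1e-9)
  }
})

test_that("varus-valgus singularity is reported", {
  T <- compose_jcs(joint_state(varus = 89.9999999))
  expect_error(decompose_jcs(rigid_pose(rotvec_to_matrix(c(0, pi / 2, 0)), c(0, 0, 0))),
               "singular")
})

test_that("noise-free trajectories resample to the profile values", {
  subj <- synthetic_subject(seed = 11, subject_sd = 0,
                            threshold_range = NULL)
  states <- cbind(time = subj$truth$time,
                  subj$truth[, c("flexion", "varus", "external",
                                 "posterior", "medial", "superior")])
  fs <- smooth_and_resample(states, "flexion")
  # per-angle values match the piecewise-linear truth closely
  prof <- default_profile(maxflex = subj$maxflex)
  for (a in c(110, 120, 140)) {
    truth <- eval_profile(prof$curves$flexion$posterior, a)
    got <- fs$posterior[!fs$is_maxflex & fs$angle == a]
    expect_lt(abs(got - truth), 0.05)
  }
  # grid angles beyond the subject's range are missing, maxflex row present
  expect_true(all(is.na(fs$posterior[fs$angle > attr(fs, "maxflex") &
                                       !fs$is_maxflex])))
  expect_false(fs$missing[fs$is_maxflex])
  expect_lte(attr(fs, "maxflex"), subj$maxflex + 1e-6)
})

test_that("resampling never extrapolates beyond observed flexion", {
  set.seed(20)
  for (s in 1:5) {
    subj <- synthetic_subject(seed = 300 + s, threshold_range = NULL)
    states <- cbind(time = subj$truth$time,
                    subj$truth[, c("flexion", "posterior", "varus",
                                   "external", "medial", "superior")])
    for (ph in c("flexion", "extension")) {
      ps <- smooth_and_resample(states, ph)
      obs_range <- range(states$flexion)
      present <- ps$angle[!ps$missing]
      expect_true(all(present >= obs_range[1] - 1e-6 &
                        present <= attr(ps, "maxflex") + 1e-6))
      expect_true(all(is.na(ps$posterior[ps$missing])))
    }
  }
})

test_that("smoothing rejects degenerate phases", {
  states <- data.frame(time = 1:4 / 5, flexion = c(100, 110, 120, 130),
                       posterior = 0)
  expect_error(smooth_and_resample(states, "flexion"), "5 frames")
  states <- data.frame(time = 1:8 / 5, flexion = seq(100, 104, length.out = 8),
                       posterior = 0)
  expect_error(smooth_and_resample(states, "flexion"), "10 degrees")
})

test_that("kinematic range is exact arithmetic on the grid endpoints", {
  tb <- kneeling_tables()$ap_ie
  ser <- data.frame(angle = tb$angle, is_maxflex = tb$is_maxflex,
                    posterior = tb$posterior_flex)
  expect_equal(as.numeric(kinematic_range(ser, "posterior",
                                          phase = "flexion")), 37.5)
  ser$posterior <- tb$posterior_ext
  expect_equal(as.numeric(kinematic_range(ser, "posterior",
                                          phase = "extension")), -36.4)
  # constant series has zero range
  ser$posterior <- 5
  expect_equal(as.numeric(kinematic_range(ser, "posterior",
                                          phase = "flexion")), 0)
  # a missing endpoint is an error
  ser$posterior[ser$angle == 100] <- NA
  expect_error(kinematic_range(ser, "posterior"), "missing")
})
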