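test_that("profile curves interpolate the printed table exactly", {
  tb <- kneeling_tables()$ap_ie
  curve <- build_profile_from_table(
    data.frame(angle = tb$angle, value = tb$posterior_flex,
               is_maxflex = tb$is_maxflex), maxflex = 161.3)
  expect_equal(eval_profile(curve, 100), -5.6)
  expect_equal(eval_profile(curve, 102.5), (-5.6 + -3.7) / 2)
  expect_error(eval_profile(curve, 95), "interpolation only")
  expect_error(eval_profile(curve, 162), "interpolation only")
  # maxflex row is remapped to the subject's maximum flexion
  expect_equal(eval_profile(curve, 161.3), 31.9)
  c2 <- build_profile_from_table(
    data.frame(angle = tb$angle, value = tb$posterior_flex,
               is_maxflex = tb$is_maxflex), maxflex = 158)
  expect_equal(eval_profile(c2, 158), 31.9)
})

test_that("profile construction rejects bad tables", {
  expect_error(build_profile_from_table(
    data.frame(angle = c(100, 100), value = c(1, 2))), "duplicate")
  expect_error(build_profile_from_table(
    data.frame(angle = 100, value = 1)), "nrow")
})

test_that("trajectories start at 90 degrees and follow the table shape", {
  prof <- default_profile(maxflex = 161.3)
  tr <- generate_trajectory(prof, n_frames = 141, subject_sd = 0, seed = 1)
  expect_equal(tr$flexion[1], 90)
  expect_equal(tr$flexion[nrow(tr)], 90)
  expect_equal(max(tr$flexion), 161.3)
  # at the frame nearest flexion 140 in the flexion phase, AP and IE match
  # the printed 140-degree row (the profile is piecewise linear, so an
  # exactly hit angle reproduces the printed means)
  i <- which(tr$phase == "flexion")[which.min(abs(
    tr$flexion[tr$phase == "flexion"] - 140))]
  expect_lt(abs(tr$flexion[i] - 140), 0.26)
  expect_lt(abs(tr$posterior[i] - 14.8), 0.2)
  expect_lt(abs(tr$external[i] - 12.5), 0.2)
})

test_that("trajectories are deterministic given the seed and monotone per phase", {
  prof <- default_profile(maxflex = 158)
  t1 <- generate_trajectory(prof, 35, subject_sd = default_subject_sd(),
                            seed = 99)
  t2 <- generate_trajectory(prof, 35, subject_sd = default_subject_sd(),
                            seed = 99)
  expect_identical(t1, t2)
  t3 <- generate_trajectory(prof, 35, subject_sd = default_subject_sd(),
                            seed = 100)
  expect_false(identical(t1$posterior, t3$posterior))
  ph <- split_phases(t1)
  expect_true(all(diff(t1$flexion[ph$flexion]) > 0))
  expect_true(all(diff(t1$flexion[ph$extension]) < 0))
})

test_that("subject offsets shift every frame of a DOF by a constant", {
  prof <- default_profile(maxflex = 161.3)
  base <- generate_trajectory(prof, 35, subject_sd = 0, seed = 4)
  noisy <- generate_trajectory(prof, 35,
                               subject_sd = c(posterior = 3, external = 0,
                                              superior = 0, varus = 0,
                                              medial = 0), seed = 4)
  d <- noisy$posterior - base$posterior
  expect_lt(diff(range(d)), 1e-9)
  expect_gt(abs(d[1]), 1e-6)
  expect_equal(noisy$external, base$external)
})

test_that("generated bones carry analytic landmarks on the mesh", {
  bones <- generate_bone_meshes()
  fem <- bones$femur
  expect_true(mesh_is_watertight(fem$mesh))
  expect_true(mesh_is_watertight(bones$tibia$mesh))
  # posterior condyle landmarks share y and z by construction symmetry,
  # so the femoral X axis is the exact lateral->medial direction
  pm <- fem$landmarks$posterior_condyle_medial
  pl <- fem$landmarks$posterior_condyle_lateral
  expect_equal(pm[2:3], pl[2:3])
  expect_equal(bone_frame(fem)$R, diag(3), ignore_attr = TRUE)
  # most posterior vertex of the medial condyle = centre + r * (-y),
  # against a brute-force argmin over the mesh vertices
  ctr <- fem$landmarks$condyle_centre_medial
  r <- sqrt(sum((pm - ctr)^2))
  near <- fem$mesh$vertices[abs(fem$mesh$vertices[, 1] - ctr[1]) < r + 1e-6 &
                              fem$mesh$vertices[, 3] < 60, , drop = FALSE]
  post <- near[which.min(near[, 2]), ]
  expect_equal(post, ctr + c(0, -r, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("bad shape parameters are rejected", {
  sh <- default_shape_params()
  sh$condyle_radius <- -1
  expect_error(generate_bone_meshes(sh), "positive")
  sh <- default_shape_params()
  sh$condyle_offset <- 0
  expect_error(generate_bone_meshes(sh), "coincide")
})

test_that("synthetic subjects are self-consistent and reproducible", {
  s1 <- synthetic_subject(seed = 31)
  s2 <- synthetic_subject(seed = 31)
  expect_identical(s1$truth, s2$truth)
  expect_equal(s1$bones$femur$mesh$vertices, s2$bones$femur$mesh$vertices)
  ff <- bone_frame(s1$bones$femur)
  tf <- bone_frame(s1$bones$tibia)
  # stored truth equals decompose_jcs of the truth poses at every frame
  for (i in seq(1, nrow(s1$truth), by = 7)) {
    T <- relative_pose(s1$poses[[i]]$femur, s1$poses[[i]]$tibia, ff, tf)
    js <- decompose_jcs(T)
    for (d in c("flexion", "varus", "external", "posterior", "medial",
                "superior"))
      expect_equal(js[[d]], s1$truth[[d]][i], tolerance = 1e-9)
  }
  expect_equal(nrow(s1$truth),
               floor(7 * s1$geom$frame_rate))
})
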