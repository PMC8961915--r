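test_that("sphere-above-plane proximity matches the closed form", {
  tib <- flat_tibia()
  r <- 25
  h <- 31   # centre height: gap = h - r = 6
  fem <- sphere_femur(c(20, -5, h), r, n = 64)
  T <- identity_placement(fem, tib)
  pm <- proximity_map(fem, tib, T)
  expect_equal(nrow(pm), nrow(tib$mesh$faces))
  expect_true(all(pm$dist >= 0))
  # the polyhedral sphere is inscribed: the minimum distance sits between
  # the exact gap and gap + chord sag
  sag <- r * (1 - cos(pi / 34))
  expect_gte(min(pm$dist), h - r - 1e-9)
  expect_lte(min(pm$dist), h - r + sag + 0.05)
})

test_that("receding the femur raises distances by exactly the offset", {
  tib <- flat_tibia()
  fem <- sphere_femur(c(15, 0, 30), 22, n = 48)
  T0 <- identity_placement(fem, tib)
  T5 <- pose_compose(rigid_pose(diag(3), c(0, 0, 5)), T0)
  d0 <- proximity_map(fem, tib, T0)$dist
  d5 <- proximity_map(fem, tib, T5)$dist
  # plateau-top faces move exactly 5 mm further; no face moves more
  expect_lte(max(d5 - d0), 5 + 1e-9)
  # nearest polyhedral facet can change slightly as the gap grows
  expect_equal(min(d5), min(d0) + 5, tolerance = 2e-3)
})

test_that("identical meshes at identity placement touch at distance zero", {
  tib <- flat_tibia(half = 20, step = 2)
  pm <- proximity_map(
    structure(list(mesh = tib$mesh, landmarks = aligned_femur_landmarks(),
                   side = "right", bone = "femur"), class = "bone_model"),
    tib, rigid_pose())
  expect_equal(min(pm$dist), 0, tolerance = 1e-9)
})

test_that("threshold selection returns the constructed worst-case gap", {
  # sphere poles placed exactly above tibial face centroids, so the
  # minimum proximity distance equals the constructed gap exactly
  tib <- flat_tibia()
  # pole-aligned face centroids differ per side because each grid cell is
  # split along a fixed diagonal
  cm <- c(88 / 3, -4 / 3)
  cl <- c(-88 / 3, -2 / 3)
  mk <- function(gm, gl) {
    fem <- bone_model(
      mesh_combine(mesh_sphere(c(cm, 20 + gm), 20, 48, 26),
                   mesh_sphere(c(cl, 20 + gl), 20, 48, 26)),
      list(notch_mid_distal = c(0, 0, 20),
           posterior_condyle_medial = c(cm[1], cm[2] - 20, 20 + gm),
           posterior_condyle_lateral = c(cl[1], cl[2] - 20, 20 + gl),
           femoral_head_centre = c(0, 0, 40)),
      bone = "femur")
    proximity_map(fem, tib, identity_placement(fem, tib))
  }
  # both condyles exactly 6.0 mm above the plateau in every frame
  maps <- list(mk(6, 6), mk(6, 6))
  expect_equal(suppressWarnings(select_threshold(maps)), 6.0)
  # worst frames: medial 5.6, lateral 6.8 -> max of the minima
  maps2 <- list(mk(5.6, 6.8), mk(5.5, 6.0))
  expect_equal(suppressWarnings(select_threshold(maps2)), 6.8)
  # no admissible threshold
  expect_error(select_threshold(list(mk(3, 12))), "threshold failure")
  # warning outside the in vivo range
  expect_warning(select_threshold(list(mk(4, 4))), "outside the in vivo")
})

test_that("per-subject thresholds land in the in vivo 5.5-7.0 mm band", {
  for (s in 1:3) {
    subj <- synthetic_subject(seed = 400 + s)
    maps <- lapply(seq_len(nrow(subj$truth)), function(i)
      proximity_map(subj$bones$femur, subj$bones$tibia,
                    compose_jcs(subj$truth[i, ])))
    d <- suppressWarnings(select_threshold(maps))
    expect_gte(d, 5.5)
    expect_lte(d, 7.0)
  }
})

test_that("contact points sit at the analytic contact location", {
  tib <- flat_tibia()
  r <- 25
  fem <- sphere_femur(c(20, -5, r + 4), r, n = 64)
  pm <- proximity_map(fem, tib, identity_placement(fem, tib))
  cp <- contact_points(pm, 6)
  # contact faces are symmetric about the touch point (20, -5); one face
  # diameter of the plateau grid is ~2.8 mm
  expect_false(cp$medial$empty)
  expect_equal(cp$medial$x, 20, tolerance = 2.9)
  expect_equal(cp$medial$y, -5, tolerance = 2.9)
  expect_true(cp$lateral$empty)
  expect_equal(cp$lateral$area, 0)
  # a threshold below every distance leaves both compartments empty
  cp0 <- contact_points(pm, 1)
  expect_true(cp0$medial$empty && cp0$lateral$empty)
})

test_that("contact of two symmetric condyles is mirror-symmetric", {
  tib <- flat_tibia()
  r <- 22
  fem <- bone_model(mesh_combine(mesh_sphere(c(20, 0, r + 5), r, 48, 26),
                                 mesh_sphere(c(-20, 0, r + 5), r, 48, 26)),
                    list(notch_mid_distal = c(0, 0, r + 5),
                         posterior_condyle_medial = c(20, -r, r + 5),
                         posterior_condyle_lateral = c(-20, -r, r + 5),
                         femoral_head_centre = c(0, 0, 2 * r)),
                    bone = "femur")
  cp <- contact_points(proximity_map(fem, tib, identity_placement(fem, tib)),
                       6.5)
  expect_gt(cp$medial$x, 0)
  expect_lt(cp$lateral$x, 0)
  # cell triangulation uses a fixed diagonal, so mirror symmetry holds
  # only up to one face
  expect_equal(cp$medial$x, -cp$lateral$x, tolerance = 0.3)
  expect_equal(cp$medial$y, cp$lateral$y, tolerance = 0.3)
  expect_equal(cp$medial$area, cp$lateral$area, tolerance = 0.02)
})

test_that("contact area is monotone non-decreasing in the threshold", {
  subj <- synthetic_subject(seed = 77)
  pm <- proximity_map(subj$bones$femur, subj$bones$tibia,
                      compose_jcs(subj$truth[10, ]))
  areas <- vapply(seq(1, 10, by = 0.5), function(d) {
    cp <- contact_points(pm, d)
    cp$medial$area + cp$lateral$area
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("sphere-on-plane CP converges to the projected centre with resolution", {
  # the whole contact patch must sit inside one compartment: centre at
  # (12, -7) keeps the ~11 mm patch clear of the midline split
  r <- 25
  errs <- vapply(c(3, 2, 1), function(step) {
    tib <- flat_tibia(half = 34, step = step)
    fem <- sphere_femur(c(12, -7, r + 4), r, n = 96)
    cp <- contact_points(proximity_map(fem, tib,
                                       identity_placement(fem, tib)), 6)
    sqrt((cp$medial$x - 12)^2 + (cp$medial$y + 7)^2)
  }, numeric(1))
  expect_lt(errs[3], max(errs[1], 0.25))
  expect_lt(errs[3], 1)
})

test_that("cp_series resamples a Table-shaped contact trajectory", {
  # synthetic medial/lateral CP trajectories shaped by the printed
  # lateral-CP flexion column, driven by a noise-free flexion sweep
  tb <- kneeling_tables()
  subj <- synthetic_subject(seed = 6, subject_sd = 0,
                            threshold_range = NULL)
  states <- cbind(time = subj$truth$time,
                  subj$truth[, c("flexion", "varus", "external",
                                 "posterior", "medial", "superior")])
  mkcurve <- function(df, col, phase)
    build_profile_from_table(data.frame(angle = df$angle,
                                        value = df[[col]],
                                        is_maxflex = df$is_maxflex),
                             maxflex = subj$maxflex)
  phase_of <- subj$truth$phase
  med <- lat <- numeric(nrow(states))
  for (ph in c("flexion", "extension")) {
    i <- phase_of == ph
    suffix <- if (ph == "flexion") "anterior_flex" else "anterior_ext"
    med[i] <- eval_profile(mkcurve(tb$medial_cp, suffix), states$flexion[i],
                           extend = TRUE)
    lat[i] <- eval_profile(mkcurve(tb$lateral_cp, suffix), states$flexion[i],
                           extend = TRUE)
  }
  cpf <- data.frame(time = states$time, medial_y = med, lateral_y = lat)
  fs <- cp_series(cpf, states, phase = "flexion")
  es <- cp_series(cpf, states, phase = "extension")
  # printed values at 140 degrees and the Range rows
  # 140 degrees is the kink of the printed medial-CP curve; match it to
  # the table's printed precision
  expect_lt(abs(fs$medial_y[!fs$is_maxflex & fs$angle == 140] - 1.1), 0.1)
  expect_lt(abs(as.numeric(kinematic_range(fs, "lateral_y")) + 14.2), 0.2)
  expect_lt(abs(as.numeric(kinematic_range(fs, "medial_y")) + 3.4), 0.2)
  expect_lt(abs(as.numeric(kinematic_range(es, "medial_y")) - 8.6), 0.2)
  expect_lt(abs(as.numeric(kinematic_range(es, "lateral_y")) - 9.8), 0.2)
  # a constant trajectory has zero range
  cpc <- data.frame(time = states$time, medial_y = 2, lateral_y = -3)
  cs <- cp_series(cpc, states, phase = "flexion")
  expect_equal(as.numeric(kinematic_range(cs, "medial_y")), 0,
               tolerance = 1e-6)
})
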