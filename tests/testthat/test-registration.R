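# brute-force oracle for the mean symmetric contour distance: nearest
# boundary-pixel distances computed directly in R
contour_dist_oracle <- function(A, B) {
  boundary <- function(M) {
    n <- nrow(M); m <- ncol(M)
    P <- matrix(0L, n + 2, m + 2)
    P[2:(n + 1), 2:(m + 1)] <- M
    fg <- P[2:(n + 1), 2:(m + 1)] != 0
    bd <- fg & (P[1:n, 2:(m + 1)] == 0 | P[3:(n + 2), 2:(m + 1)] == 0 |
                  P[2:(n + 1), 1:m] == 0 | P[2:(n + 1), 3:(m + 2)] == 0)
    which(bd, arr.ind = TRUE)
  }
  ba <- boundary(A)
  bb <- boundary(B)
  dmin <- function(P, Q) {
    vapply(seq_len(nrow(P)), function(i)
      sqrt(min((Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2)), numeric(1))
  }
  0.5 * (mean(dmin(ba, bb)) + mean(dmin(bb, ba)))
}

shift_mask <- function(M, dx) {
  S <- matrix(0L, nrow(M), ncol(M))
  S[(1 + dx):nrow(M), ] <- M[1:(nrow(M) - dx), ]
  S
}

test_that("silhouette cost is zero iff masks are identical, and symmetric", {
  m <- matrix(0L, 64, 64)
  m[20:40, 15:35] <- 1L
  expect_equal(as.numeric(silhouette_cost(m, m)), 0)
  s <- shift_mask(m, 5)
  expect_gt(as.numeric(silhouette_cost(m, s)), 0)
  expect_equal(as.numeric(silhouette_cost(m, s)),
               as.numeric(silhouette_cost(s, m)))
  expect_error(silhouette_cost(m, matrix(0L, 32, 32)), "mismatch")
  expect_error(silhouette_cost(matrix(0L, 64, 64), m), "empty")
})

test_that("disjoint masks have IoU term equal to one", {
  a <- matrix(0L, 64, 64)
  b <- matrix(0L, 64, 64)
  a[5:15, 5:15] <- 1L
  b[40:50, 40:50] <- 1L
  co <- silhouette_cost(a, b, w_iou = 1, w_contour = 0)
  expect_equal(as.numeric(co), 1)
  expect_equal(attr(co, "iou"), 0)
})

test_that("contour distance matches the brute-force oracle", {
  set.seed(9)
  # a square, a disc, and a random blob, each against a shifted copy
  masks <- list()
  sq <- matrix(0L, 80, 80); sq[20:60, 25:55] <- 1L
  masks$square <- sq
  dc <- matrix(0L, 80, 80)
  for (i in 1:80) for (j in 1:80)
    if ((i - 40)^2 + (j - 40)^2 <= 18^2) dc[i, j] <- 1L
  masks$disc <- dc
  for (nm in names(masks)) {
    A <- masks[[nm]]
    B <- shift_mask(A, 3)
    got <- attr(silhouette_cost(A, B), "contour_dist")
    expect_equal(got, contour_dist_oracle(A, B), tolerance = 1e-9)
  }
  # for the axis-aligned square the directed distances are 3 on the two
  # advancing edges and 0 along the sides, bounded by the shift itself
  sq_cd <- attr(silhouette_cost(sq, shift_mask(sq, 3)), "contour_dist")
  expect_lte(sq_cd, 3 + 1e-9)
  expect_gt(sq_cd, 1)
})

test_that("the fused optimizer cost equals the public cost exactly", {
  geom <- small_geom()
  bones <- generate_bone_meshes()
  subj_pose <- rigid_pose(rotvec_to_matrix(c(100 * pi / 180, 0, 0)), c(0, 0, -geom$sod))
  obs <- render_silhouette(bones$femur, subj_pose, geom)
  ctl <- reg_control()
  f <- kneelkin:::reg_cost_fun(bones$femur$mesh, obs, geom, ctl)
  for (dz in c(0, 2, -4)) {
    p2 <- rigid_pose(rotvec_to_matrix(c(0.01, -0.02, 0.015)) %*% subj_pose$R,
                     subj_pose$t + c(1, -2, dz))
    rend <- render_silhouette(bones$femur, p2, geom)
    expect_equal(f(p2$R, p2$t),
                 as.numeric(silhouette_cost(obs, rend, ctl$w_iou,
                                            ctl$w_contour)),
                 tolerance = 1e-12)
  }
})

test_that("registration from the true pose returns it unchanged at cost 0", {
  geom <- small_geom()
  bones <- generate_bone_meshes()
  truth <- rigid_pose(rotvec_to_matrix(c(110 * pi / 180, 0, 0)), c(5, -3, -geom$sod))
  obs <- silhouette_observation(render_silhouette(bones$femur, truth, geom),
                                geom)
  rec <- register_frame(bones$femur, obs, truth)
  expect_pose_equal(rec, truth, tol = 1e-12)
  expect_equal(rec$cost, 0)
  expect_true(rec$converged)
})

test_that("a perturbed initialization is recovered on small images", {
  # coarse-image variant of the accuracy experiment (the full-resolution
  # bounds are asserted in the acceptance suite)
  geom <- small_geom()
  bones <- generate_bone_meshes()
  truth <- rigid_pose(rotvec_to_matrix(c(120 * pi / 180, 0, 0)), c(4, 8, -geom$sod))
  obs <- silhouette_observation(render_silhouette(bones$femur, truth, geom),
                                geom)
  set.seed(3)
  init <- rigid_pose(rotvec_to_matrix(c(0.02, 0.02, -0.015)) %*% truth$R,
                     truth$t + c(1.5, -1.3, 0))
  rec <- register_frame(bones$femur, obs, init)
  dt <- rec$t - truth$t
  expect_lt(sqrt(dt[1]^2 + dt[2]^2), 0.6)
  rot_err <- sqrt(sum(matrix_to_rotvec(t(truth$R) %*% rec$R)^2)) * 180 / pi
  expect_lt(rot_err, 0.8)
})

test_that("registration without overlap fails loudly, multi-start rescues moderate offsets", {
  geom <- small_geom(128)
  sph <- sphere_femur(c(0, 0, 0), 20, 32)
  truth <- rigid_pose(diag(3), c(0, 0, -geom$sod))
  obs <- silhouette_observation(render_silhouette(sph, truth, geom), geom)
  hopeless <- rigid_pose(diag(3), c(500, 500, -geom$sod))
  expect_error(register_frame(sph, obs, hopeless,
                              reg_control(multi_start = 2)),
               "registration failure")
})

test_that("tracking a constant-pose stack returns constant poses", {
  geom <- small_geom()
  bones <- generate_bone_meshes()
  truth <- rigid_pose(rotvec_to_matrix(c(100 * pi / 180, 0, 0)), c(0, 0, -geom$sod))
  obs <- silhouette_observation(render_silhouette(bones$femur, truth, geom),
                                geom)
  poses <- track_sequence(bones$femur, list(obs, obs, obs), truth)
  for (p in poses) expect_pose_equal(p, truth, tol = 1e-12)
})

test_that("pose CSV output has one row per frame with finite values", {
  poses <- list(rigid_pose(diag(3), c(1, 2, 3), cost = 0.1,
                           converged = TRUE),
                rigid_pose(rotvec_to_matrix(c(0, 0, 0.3)), c(4, 5, 6), cost = 0.2,
                           converged = TRUE))
  f <- tempfile(fileext = ".csv")
  write_poses_csv(poses, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 2)
  expect_true(all(is.finite(as.matrix(df[, c("rx", "ry", "rz", "tx", "ty",
                                             "tz", "cost")]))))
  expect_equal(df$tz, c(3, 6))
})
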