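# shared fixtures, all built in code

# flat-plateau tibia for analytic contact fixtures
flat_tibia <- function(half = 40, step = 2, z_bottom = -10) {
  g <- seq(-half, half, step)
  mesh <- mesh_heightfield_slab(g, g, function(x, y) rep(0, length(x)),
                                z_bottom)
  lm <- list(ridge_apex = c(0, 0, 0),
             condyle_mid_medial = c(half / 2, 0, 0),
             condyle_mid_lateral = c(-half / 2, 0, 0),
             ankle_centre = c(0, 0, z_bottom))
  bone_model(mesh, lm, bone = "tibia")
}

# sphere "femur" with its frame axes aligned to the lab
sphere_femur <- function(centre, r, n = 48) {
  mesh <- mesh_sphere(centre, r, n, n %/% 2 + 2)
  lm <- list(notch_mid_distal = centre,
             posterior_condyle_medial = centre + c(2, -r, 0),
             posterior_condyle_lateral = centre + c(-2, -r, 0),
             femoral_head_centre = centre + c(0, 0, r))
  bone_model(mesh, lm, bone = "femur")
}

# identity placement transform for fixtures built directly in tibia-local
# coordinates
identity_placement <- function(femur, tibia) {
  pose_compose(pose_invert(bone_frame(tibia)), bone_frame(femur))
}

# small projection geometry for fast rendering in tests
small_geom <- function(n = 256) {
  projection_geometry(image_size = c(n, n), pixel_pitch = 431.8 / n)
}

# landmarks of an axis-aligned femur/tibia
aligned_femur_landmarks <- function() {
  list(notch_mid_distal = c(0, 0, 0),
       posterior_condyle_medial = c(30, -20, 0),
       posterior_condyle_lateral = c(-30, -20, 0),
       femoral_head_centre = c(0, 0, 100))
}

aligned_tibia_landmarks <- function() {
  list(ridge_apex = c(0, 0, 0),
       condyle_mid_medial = c(25, 0, -2),
       condyle_mid_lateral = c(-25, 0, -2),
       ankle_centre = c(0, 0, -120))
}

transform_landmarks <- function(lm, R, t) {
  lapply(lm, function(p) as.numeric(R %*% p) + t)
}

random_joint_state <- function() {
  joint_state(flexion = runif(1, -170, 170), varus = runif(1, -70, 70),
              external = runif(1, -170, 170), posterior = rnorm(1, 0, 20),
              medial = rnorm(1, 0, 20), superior = rnorm(1, 0, 20))
}

expect_pose_equal <- function(p, q, tol = 1e-9) {
  expect_lt(max(abs(p$R - q$R)), tol)
  expect_lt(max(abs(p$t - q$t)), tol)
}
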