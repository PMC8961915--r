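#' Bone models
#'
#' A closed triangle mesh plus named anatomical landmarks for one bone.
#' Landmarks are bone-local 3D points (mm) and must include everything the
#' frame construction needs.
#'
#' @param mesh a `knee_mesh`.
#' @param landmarks named list of 3D points.
#' @param side `"right"` or `"left"`.
#' @param bone `"femur"` or `"tibia"`.
#' @return An object of class `bone_model`.
#' @export
bone_model <- function(mesh, landmarks, side = c("right", "left"),
                       bone = c("femur", "tibia")) {
  side <- match.arg(side)
  bone <- match.arg(bone)
  if (!mesh_is_watertight(mesh))
    stop("construction error: bone mesh is not watertight")
  need <- if (bone == "femur")
    c("notch_mid_distal", "posterior_condyle_medial",
      "posterior_condyle_lateral", "femoral_head_centre")
  else c("ridge_apex", "condyle_mid_medial", "condyle_mid_lateral",
         "ankle_centre")
  check_landmarks(landmarks, need)
  bb_lo <- apply(mesh$vertices, 2, min) - 1e-9
  bb_hi <- apply(mesh$vertices, 2, max) + 1e-9
  for (nm in names(landmarks)) {
    p <- landmarks[[nm]]
    if (any(p < bb_lo) || any(p > bb_hi))
      stop("landmark '", nm, "' lies outside the mesh bounding box")
  }
  structure(list(mesh = mesh, landmarks = landmarks, side = side,
                 bone = bone),
            class = "bone_model")
}

#' @export
print.bone_model <- function(x, ...) {
  cat("<bone_model>", x$side, x$bone, "-", nrow(x$mesh$vertices),
      "vertices,", nrow(x$mesh$faces), "faces,",
      length(x$landmarks), "landmarks\n")
  invisible(x)
}

#' Mirror a bone model across x = 0 (left/right convention swap)
#' @param bone a `bone_model`.
#' @return The mirrored `bone_model` with the opposite `side` label.
#' @export
mirror_bone <- function(bone) {
  lm <- lapply(bone$landmarks, function(p) p * c(-1, 1, 1))
  bone_model(mesh_mirror_x(bone$mesh), lm,
             side = if (bone$side == "right") "left" else "right",
             bone = bone$bone)
}

#' Default shape parameters of the synthetic knee
#'
#' Coarse geometric primitives (spheres, cylinders, a height-field slab)
#' stand in for segmented bone: the analysis depends only on rigid shape
#' plus landmarks, and primitives make every landmark and contact fixture
#' analytic. All values in mm.
#' @return Named list of construction parameters.
#' @export
default_shape_params <- function() {
  list(condyle_radius = 40, condyle_offset = 40, condyle_z = 0,
       femur_shaft_radius = 13, femur_shaft_y = 20,
       femur_shaft_z = c(20, 118),
       head_radius = 24, head_z = 130,
       plateau_half_x = 55, plateau_y = c(-40, 20), plateau_top_z = -2,
       plateau_bottom_z = -16, ridge_height = 2, ridge_sigma = c(6, 8),
       facet_depth = 1.2, facet_sigma = 10, facet_y = 0,
       tibia_shaft_radius = 15, tibia_length = 150, ankle_radius = 12,
       sphere_res = c(28, 18), plateau_res = c(45, 25))
}

#' Generate parametric femur and tibia meshes with analytic landmarks
#'
#' The femur is two condylar spheres centred on the flexion axis, an
#' anteriorly bowed shaft cylinder and a proximal head sphere; the tibia
#' is a plateau slab with two shallow concave
#' facets and a central intercondylar ridge, a shaft cylinder and an
#' ankle marker sphere. Landmarks are returned analytically from the
#' construction parameters, so every downstream frame and contact fixture
#' has a closed form.
#'
#' @param shape named list as from [default_shape_params()].
#' @param side `"right"` (default) or `"left"` (mirrored across x = 0).
#' @return list with `femur` and `tibia` `bone_model`s.
#' @export
generate_bone_meshes <- function(shape = default_shape_params(),
                                 side = c("right", "left")) {
  side <- match.arg(side)
  s <- shape
  if (s$condyle_radius <= 0 || s$head_radius <= 0 ||
      s$femur_shaft_radius <= 0 || s$tibia_shaft_radius <= 0)
    stop("parameter error: radii must be positive")
  if (s$condyle_offset <= 0)
    stop("parameter error: medial and lateral condyle centres coincide")
  res <- s$sphere_res
  cm <- c(s$condyle_offset, 0, s$condyle_z)
  cl <- c(-s$condyle_offset, 0, s$condyle_z)
  femur_mesh <- mesh_combine(
    mesh_sphere(cm, s$condyle_radius, res[1], res[2]),
    mesh_sphere(cl, s$condyle_radius, res[1], res[2]),
    mesh_cylinder(s$femur_shaft_radius, s$femur_shaft_z[1],
                  s$femur_shaft_z[2], centre_xy = c(0, s$femur_shaft_y),
                  n_theta = res[1]),
    mesh_sphere(c(0, 0, s$head_z), s$head_radius, res[1], res[2]))
  femur_lm <- list(
    notch_mid_distal = c(0, 0, 0),
    posterior_condyle_medial = cm + c(0, -s$condyle_radius, 0),
    posterior_condyle_lateral = cl + c(0, -s$condyle_radius, 0),
    femoral_head_centre = c(0, 0, s$head_z),
    condyle_centre_medial = cm,
    condyle_centre_lateral = cl)

  top_fun <- function(x, y) {
    s$plateau_top_z +
      s$ridge_height * exp(-x^2 / (2 * s$ridge_sigma[1]^2) -
                             y^2 / (2 * s$ridge_sigma[2]^2)) -
      s$facet_depth * (exp(-((x - s$condyle_offset)^2 +
                               (y - s$facet_y)^2) / (2 * s$facet_sigma^2)) +
                         exp(-((x + s$condyle_offset)^2 +
                                 (y - s$facet_y)^2) / (2 * s$facet_sigma^2)))
  }
  pres <- s$plateau_res
  xs <- seq(-s$plateau_half_x, s$plateau_half_x, length.out = pres[1])
  ys <- seq(s$plateau_y[1], s$plateau_y[2], length.out = pres[2])
  tibia_mesh <- mesh_combine(
    mesh_heightfield_slab(xs, ys, top_fun, s$plateau_bottom_z),
    mesh_cylinder(s$tibia_shaft_radius, -s$tibia_length,
                  s$plateau_bottom_z, n_theta = res[1]),
    mesh_sphere(c(0, 0, -s$tibia_length), s$ankle_radius, res[1], res[2]))
  tibia_lm <- list(
    ridge_apex = c(0, 0, top_fun(0, 0)),
    condyle_mid_medial = c(s$condyle_offset, s$facet_y,
                           top_fun(s$condyle_offset, s$facet_y)),
    condyle_mid_lateral = c(-s$condyle_offset, s$facet_y,
                            top_fun(-s$condyle_offset, s$facet_y)),
    ankle_centre = c(0, 0, -s$tibia_length))

  femur <- bone_model(femur_mesh, femur_lm, side = "right", bone = "femur")
  tibia <- bone_model(tibia_mesh, tibia_lm, side = "right", bone = "tibia")
  if (side == "left") {
    femur <- mirror_bone(femur)
    tibia <- mirror_bone(tibia)
  }
  list(femur = femur, tibia = tibia)
}

#' Generate a ground-truth joint-state trajectory
#'
#' Flexion sweeps from 90 degrees to the subject's maximum flexion and back
#' to 90 at a constant angular rate within each phase; the other DOFs are
#' evaluated from the phase's profile curve at the current flexion angle
#' (boundary segments extended linearly below the profile's first
#' tabulated angle) plus a per-subject Gaussian constant offset drawn once
#' per DOF.
#' Deterministic given `seed`.
#'
#' @param profile a `trajectory_profile`.
#' @param n_frames number of frames (>= 4).
#' @param subject_sd named per-DOF offset SDs (0 = no variation).
#' @param seed integer seed.
#' @param white_sd optional within-trial white-noise SD applied to every
#'   non-flexion DOF sample (default 0).
#' @return data.frame with `time` (s), `phase`, and the six JCS DOFs.
#' @export
generate_trajectory <- function(profile, n_frames, subject_sd = 0, seed,
                                white_sd = 0) {
  stopifnot(n_frames >= 4)
  if (missing(seed)) stop("a seed is required")
  dofs <- c("posterior", "external", "superior", "varus", "medial")
  if (length(subject_sd) == 1 && is.null(names(subject_sd)))
    subject_sd <- stats::setNames(rep(subject_sd, length(dofs)), dofs)
  set.seed(seed)
  offs <- stats::setNames(stats::rnorm(length(dofs)) *
                            subject_sd[dofs], dofs)
  offs[is.na(offs)] <- 0
  dur <- profile$duration_s
  half <- dur / 2
  time <- seq(0, dur, length.out = n_frames)
  phase <- ifelse(time <= half, "flexion", "extension")
  flex <- ifelse(time <= half,
                 90 + (profile$maxflex - 90) * time / half,
                 90 + (profile$maxflex - 90) * (dur - time) / half)
  out <- data.frame(time = time, phase = phase, flexion = flex)
  for (d in dofs) {
    v <- numeric(n_frames)
    for (ph in c("flexion", "extension")) {
      i <- phase == ph
      cv <- profile$curves[[ph]][[d]]
      v[i] <- if (is.null(cv)) 0 else eval_profile(cv, flex[i], extend = TRUE)
    }
    if (white_sd > 0) v <- v + stats::rnorm(n_frames, 0, white_sd)
    out[[d]] <- v + offs[[d]]
  }
  out
}

#' Generate one synthetic kneeling subject
#'
#' Bones, ground-truth poses (lab), ground-truth joint states, and the
#' projection geometry. The tibia is fixed in the lab with its medial axis
#' along the viewing direction (a lateral projection: tibial X -> lab z,
#' Y -> lab x, Z -> lab y) and its frame origin at the nominal object
#' plane; femoral poses follow from the joint-state trajectory. Silhouette
#' images can be rendered eagerly (`render_images = TRUE`) or on demand
#' with [render_subject_frame()].
#'
#' @param seed integer seed (drives maxflex, subject offsets).
#' @param id subject identifier.
#' @param shape shape parameters, see [default_shape_params()].
#' @param geom a `projection_geometry`.
#' @param duration_s motion duration (s); frames = floor(duration x rate).
#' @param maxflex subject maximum flexion; `NULL` draws from the cohort
#'   distribution N(161.3, 3.2^2), truncated to [155.5, 170].
#' @param subject_sd per-DOF offset SDs; defaults to the printed
#'   flexion-phase SDs, see [default_subject_sd()]. Use 0 for a noise-free
#'   subject on the mean curves.
#' @param white_sd within-trial white-noise SD (default 0).
#' @param threshold_range the in vivo contact threshold varied by subject
#'   between 5.5 and 7.0 mm; each subject's condylar radius is sized so
#'   its worst-frame condyle-plateau gap lands at a draw from this
#'   interval (the draw is kept slightly inside the band to leave room
#'   for mesh-discretization bias). `NULL` keeps the fixed default
#'   radius.
#' @param render_images render and store the silhouette stack.
#' @return An object of class `kneel_subject` with elements `bones`,
#'   `truth` (data.frame of joint states), `poses` (per-frame list with
#'   `femur` and `tibia` lab poses), `geom`, `images` (optional), `id`,
#'   `seed`, `maxflex`.
#' @export
synthetic_subject <- function(seed, id = sprintf("S%03d", seed),
                              shape = default_shape_params(),
                              geom = projection_geometry(),
                              duration_s = 7, maxflex = NULL,
                              subject_sd = default_subject_sd(),
                              white_sd = 0, threshold_range = c(5.8, 6.7),
                              render_images = FALSE) {
  set.seed(seed)
  if (is.null(maxflex))
    maxflex <- min(max(stats::rnorm(1, 161.3, 3.2), 155.5), 170)
  d_target <- if (is.null(threshold_range)) NA_real_
  else stats::runif(1, threshold_range[1], threshold_range[2])
  profile <- default_profile(maxflex = maxflex, duration_s = duration_s)
  n_frames <- floor(duration_s * geom$frame_rate)
  traj <- generate_trajectory(profile, n_frames, subject_sd = subject_sd,
                              seed = seed + 10000L, white_sd = white_sd)
  if (!is.na(d_target))
    shape$condyle_radius <- size_condyles(shape, traj, d_target)
  bones <- generate_bone_meshes(shape, side = "right")
  ff <- bone_frame(bones$femur)
  tf <- bone_frame(bones$tibia)
  # lab placement of the tibial frame: X->z, Y->x, Z->y, origin at -sod
  R_align <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  P_tf <- rigid_pose(R_align, c(0, 0, -geom$sod))
  tibia_pose <- pose_compose(P_tf, pose_invert(tf))
  poses <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    Tk <- compose_jcs(traj[i, ])
    femur_pose <- pose_compose(P_tf, pose_compose(Tk, pose_invert(ff)))
    femur_pose$frame_index <- i
    poses[[i]] <- list(femur = femur_pose, tibia = tibia_pose)
  }
  subj <- structure(list(bones = bones, truth = traj, poses = poses,
                         geom = geom, id = id, seed = seed,
                         maxflex = maxflex, images = NULL),
                    class = "kneel_subject")
  if (render_images) {
    subj$images <- lapply(seq_len(n_frames), function(i)
      list(femur = render_subject_frame(subj, i, "femur"),
           tibia = render_subject_frame(subj, i, "tibia")))
  }
  subj
}

#' @export
print.kneel_subject <- function(x, ...) {
  cat("<kneel_subject>", x$id, "-", nrow(x$truth), "frames, maxflex",
      sprintf("%.1f", x$maxflex), "deg, seed", x$seed, "\n")
  invisible(x)
}

# Condylar radius such that the subject's worst-frame (largest) condyle-
# to-plateau gap equals the target contact threshold. Centres sit on the
# femoral X axis, so the centre height in the tibia is flexion-invariant
# and only the joint-state translations and varus tilt move it.
size_condyles <- function(shape, traj, d_target) {
  worst <- -Inf
  top_fun <- function(x, y) {
    shape$plateau_top_z +
      shape$ridge_height * exp(-x^2 / (2 * shape$ridge_sigma[1]^2) -
                                 y^2 / (2 * shape$ridge_sigma[2]^2)) -
      shape$facet_depth *
        (exp(-((x - shape$condyle_offset)^2 + (y - shape$facet_y)^2) /
               (2 * shape$facet_sigma^2)) +
           exp(-((x + shape$condyle_offset)^2 + (y - shape$facet_y)^2) /
                 (2 * shape$facet_sigma^2)))
  }
  centres <- rbind(c(shape$condyle_offset, 0, shape$condyle_z),
                   c(-shape$condyle_offset, 0, shape$condyle_z))
  for (i in seq_len(nrow(traj))) {
    M <- compose_jcs(traj[i, ])
    C <- pose_apply(M, centres)
    gap <- C[, 3] - top_fun(C[, 1], C[, 2])
    worst <- max(worst, gap)
  }
  r <- worst - d_target
  if (r < 10) stop("condyle sizing failed: trajectory gap too small")
  r
}

#' Render one bone's silhouette for one frame of a synthetic subject
#' @param subject a `kneel_subject`.
#' @param i frame index.
#' @param bone `"femur"` or `"tibia"`.
#' @return Binary mask.
#' @export
render_subject_frame <- function(subject, i, bone = c("femur", "tibia")) {
  bone <- match.arg(bone)
  if (!is.null(subject$images)) return(subject$images[[i]][[bone]])
  render_silhouette(subject$bones[[bone]], subject$poses[[i]][[bone]],
                    subject$geom)
}
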