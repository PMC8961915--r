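#' Tibiofemoral proximity map
#'
#' For every tibial face, the unsigned nearest distance from its centroid
#' to the posed femoral surface (exact point-to-triangle), with centroids
#' expressed in tibial-frame coordinates so contact points live on the
#' tibial X-Y plane. This mesh-to-mesh "proximity distance" is the
#' cartilage-free surrogate for articular contact.
#'
#' @param femur,tibia `bone_model`s (frames are derived from their
#'   landmarks).
#' @param T relative transform of the femoral frame in the tibial frame
#'   (`rigid_pose`, e.g. from [relative_pose()] or [compose_jcs()]).
#' @return A data.frame of class `proximity_map`: one row per tibial face
#'   with `x`, `y`, `z` (tibial frame, mm), `area` (mm^2) and `dist` (mm).
#' @export
proximity_map <- function(femur, tibia, T) {
  if (nrow(femur$mesh$faces) == 0 || nrow(tibia$mesh$faces) == 0)
    stop("empty mesh")
  if (!all(is.finite(T$t)) || !all(is.finite(T$R))) stop("non-finite transform")
  tf <- bone_frame(tibia)
  ff <- bone_frame(femur)
  info <- mesh_face_info(tibia$mesh)
  # tibial face centroids in tibial-frame coordinates
  Ct <- pose_apply(pose_invert(tf), info$centroids)
  # femoral vertices into the same coordinates
  M <- pose_compose(T, pose_invert(ff))
  Vf <- pose_apply(M, femur$mesh$vertices)
  d <- point_mesh_dist_cpp(Ct, Vf, femur$mesh$faces)
  structure(data.frame(x = Ct[, 1], y = Ct[, 2], z = Ct[, 3],
                       area = info$areas, dist = d),
            class = c("proximity_map", "data.frame"))
}

#' Select the contact proximity-distance threshold for one subject
#'
#' The smallest threshold d on a 0.1 mm grid such that both compartments
#' show a nonempty contact area in every analysed frame (the smallest
#' proximity distance at which the contact area appears in all frames).
#' In vivo this subject-dependent threshold ranged from 5.5 to 7.0 mm; a
#' warning is issued when the selected value falls outside that interval.
#'
#' @param maps list of `proximity_map`s (all analysed frames, both phases).
#' @param grid_step threshold grid step, mm (default 0.1).
#' @param d_max largest admissible threshold, mm (default 10).
#' @return The threshold d (mm).
#' @export
select_threshold <- function(maps, grid_step = 0.1, d_max = 10) {
  if (length(maps) < 1) stop("need at least one proximity map")
  worst <- 0
  for (m in maps) {
    med <- m$dist[m$x > 0]
    lat <- m$dist[m$x < 0]
    if (!length(med) || !length(lat))
      stop("a compartment has no tibial faces")
    worst <- max(worst, min(med), min(lat))
  }
  d <- ceiling(worst / grid_step - 1e-9) * grid_step
  if (d > d_max)
    stop("threshold failure: no d <= ", d_max,
         " mm gives contact in every frame (needs ", round(d, 1), " mm)")
  if (d < 5.5 || d > 7.0)
    warning(sprintf(paste0("selected threshold %.1f mm is outside the ",
                           "in vivo range [5.5, 7.0] mm"), d))
  d
}

#' Medial and lateral contact points of one frame
#'
#' Contributing faces are those within the proximity threshold; the
#' compartments are split by the sign of the tibial-frame x of the face
#' centroid (medial = +x in the right-knee convention). The contact point
#' is the area-weighted centroid of the contributing face centroids
#' projected onto the tibial X-Y plane; an empty compartment is flagged,
#' not an error.
#'
#' @param map a `proximity_map`.
#' @param d proximity threshold, mm (> 0).
#' @return list with `medial` and `lateral`, each a list
#'   `(compartment, x, y, area, empty)`.
#' @export
contact_points <- function(map, d) {
  stopifnot(d > 0)
  one <- function(rows, name) {
    if (!nrow(rows))
      return(list(compartment = name, x = NA_real_, y = NA_real_,
                  area = 0, empty = TRUE))
    w <- rows$area
    list(compartment = name,
         x = sum(rows$x * w) / sum(w),
         y = sum(rows$y * w) / sum(w),
         area = sum(w), empty = FALSE)
  }
  hit <- map[map$dist <= d, , drop = FALSE]
  list(medial = one(hit[hit$x > 0, , drop = FALSE], "medial"),
       lateral = one(hit[hit$x < 0, , drop = FALSE], "lateral"))
}

#' Contact-point series on the flexion grid
#'
#' Smooths the per-frame contact-point anterior-posterior coordinate
#' (tibial-frame y, anterior positive) against time with the same B-spline
#' machinery as the kinematics and resamples it on the 5-degree flexion
#' grid of the given phase. Frames with an empty compartment are dropped
#' before fitting; missingness propagates to the grid.
#'
#' @param cp_frames data.frame with columns `time`, `medial_y`,
#'   `lateral_y` (NA where a compartment was empty).
#' @param states the subject's joint-state trajectory (`time`, `flexion`);
#'   supplies the flexion-time curve used for the grid inversion.
#' @param phase `"flexion"` or `"extension"`.
#' @param grid flexion grid angles (degrees).
#' @param smoothing see [smooth_and_resample()].
#' @return A `phase_series` with columns `medial_y` and `lateral_y`.
#' @export
cp_series <- function(cp_frames, states, phase = c("flexion", "extension"),
                      grid = seq(100, 155, by = 5),
                      smoothing = c("gcv", "interpolate")) {
  phase <- match.arg(phase)
  smoothing <- match.arg(smoothing)
  stopifnot(nrow(cp_frames) == nrow(states))
  merged <- cbind(states[, c("time", "flexion")],
                  cp_frames[, c("medial_y", "lateral_y"), drop = FALSE])
  ok <- stats::complete.cases(merged)
  if (sum(ok) < 5) stop("too few frames with nonempty contact points")
  smooth_and_resample(merged[ok, , drop = FALSE], phase = phase,
                      grid = grid, smoothing = smoothing,
                      values = c("medial_y", "lateral_y"))
}
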