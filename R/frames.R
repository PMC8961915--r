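#' Anatomical coordinate frames
#'
#' Femoral and tibial body-fixed frames after Grood and Suntay, built from
#' named landmarks. Conventions (right knee): +X medial, +Y anterior,
#' +Z proximal; the long axis Z is primary (it passes through two named
#' landmarks), X is the condylar direction orthogonalized against Z, and
#' Y = Z x X closes a right-handed triad. Left knees are mirrored to the
#' right-side convention before analysis.
#'
#' A frame is stored as a `rigid_pose` mapping frame coordinates to
#' bone-local coordinates (`origin` + `R %*% p`), with the axes as the
#' columns of `R`.
#'
#' @name anatomical-frames
NULL

frame_from_axes <- function(origin, X, Y, Z, bone) {
  f <- rigid_pose(cbind(X, Y, Z), origin)
  attr(f, "bone") <- bone
  class(f) <- c("anatomical_frame", class(f))
  f
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("<anatomical_frame>", attr(x, "bone"), "\n")
  cat("  origin:", paste(sprintf("%.2f", x$t), collapse = ", "), "mm\n")
  invisible(x)
}

check_landmarks <- function(lm, need) {
  miss <- setdiff(need, names(lm))
  if (length(miss))
    stop("missing landmarks: ", paste(miss, collapse = ", "))
  for (nm in need) if (length(lm[[nm]]) != 3 || !all(is.finite(lm[[nm]])))
    stop("landmark '", nm, "' is not a finite 3D point")
}

axis_pair <- function(z_raw, x_raw) {
  Z <- vhat(z_raw)
  x_perp <- x_raw - sum(x_raw * Z) * Z
  if (vnorm(x_perp) < 1e-9 * max(vnorm(x_raw), 1))
    stop("degenerate frame: condylar line is parallel to the long axis")
  X <- vhat(x_perp)
  list(X = X, Y = vcross(Z, X), Z = Z)
}

#' Build the femoral anatomical frame
#'
#' Origin at the most distal point of the intercondylar notch mid-plane;
#' Z points proximally through the femoral head centre; X is parallel to
#' the line connecting the most posterior points of the two condyles
#' (orthogonalized against Z, signed to point medially); Y = Z x X.
#'
#' @param lm named list of landmarks: `notch_mid_distal`,
#'   `posterior_condyle_medial`, `posterior_condyle_lateral`,
#'   `femoral_head_centre` (3D points, mm, bone-local).
#' @return An `anatomical_frame`.
#' @export
build_femoral_frame <- function(lm) {
  check_landmarks(lm, c("notch_mid_distal", "posterior_condyle_medial",
                        "posterior_condyle_lateral", "femoral_head_centre"))
  origin <- lm$notch_mid_distal
  z_raw <- lm$femoral_head_centre - origin
  if (vnorm(z_raw) < 1e-9) stop("head centre coincides with the origin")
  x_raw <- lm$posterior_condyle_medial - lm$posterior_condyle_lateral
  if (vnorm(x_raw) < 1e-9) stop("posterior condyle points coincide")
  ax <- axis_pair(z_raw, x_raw)
  frame_from_axes(origin, ax$X, ax$Y, ax$Z, "femur")
}

#' Build the tibial anatomical frame
#'
#' Origin at the apex of the medial-lateral intercondylar ridge; Z points
#' proximally from the ankle-joint centre through the origin; X is parallel
#' to the line connecting the midpoints of the medial and lateral tibial
#' condyles (orthogonalized against Z, signed medially); Y = Z x X.
#'
#' @param lm named list of landmarks: `ridge_apex`, `condyle_mid_medial`,
#'   `condyle_mid_lateral`, `ankle_centre` (3D points, mm, bone-local).
#' @return An `anatomical_frame`.
#' @export
build_tibial_frame <- function(lm) {
  check_landmarks(lm, c("ridge_apex", "condyle_mid_medial",
                        "condyle_mid_lateral", "ankle_centre"))
  origin <- lm$ridge_apex
  z_raw <- origin - lm$ankle_centre
  if (vnorm(z_raw) < 1e-9) stop("ankle centre coincides with the origin")
  x_raw <- lm$condyle_mid_medial - lm$condyle_mid_lateral
  if (vnorm(x_raw) < 1e-9) stop("condyle midpoints coincide")
  ax <- axis_pair(z_raw, x_raw)
  frame_from_axes(origin, ax$X, ax$Y, ax$Z, "tibia")
}

#' Anatomical frame of a bone model
#' @param bone a `bone_model`.
#' @return The femoral or tibial `anatomical_frame` built from its landmarks.
#' @export
bone_frame <- function(bone) {
  if (bone$bone == "femur") build_femoral_frame(bone$landmarks)
  else build_tibial_frame(bone$landmarks)
}

#' Write landmarks as JSON
#' @param landmarks named list of 3D points (mm).
#' @param path output file.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks, as.numeric), path, digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' Read landmarks from JSON
#' @param path JSON file written by [write_landmarks()].
#' @return Named list of 3D points.
#' @export
read_landmarks <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.numeric)
}

#' Serialize a frame (or any rigid pose) as a 4x4 homogeneous matrix in JSON
#' @param pose a `rigid_pose` or `anatomical_frame`.
#' @param path output file.
#' @export
write_pose_json <- function(pose, path) {
  H <- rbind(cbind(pose$R, pose$t), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = H), path, digits = NA)
  invisible(path)
}

#' Read a 4x4 homogeneous matrix JSON back into a rigid pose
#' @param path JSON file written by [write_pose_json()].
#' @return A `rigid_pose`.
#' @export
read_pose_json <- function(path) {
  H <- jsonlite::read_json(path, simplifyVector = TRUE)$matrix
  rigid_pose(H[1:3, 1:3], H[1:3, 4])
}
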