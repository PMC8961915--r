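#' Projection geometry of the single-plane fluoroscope
#'
#' Point X-ray source with a flat detector. The canonical lab frame puts
#' the source at the origin looking along -z: the detector plane sits at
#' z = -`sid` with pixel axes u = +x, v = +y, and the knee is placed near
#' z = -`sod`. The detector defaults emulate a 17-inch (431.8 mm) flat
#' panel sampled at 1024 x 1024 pixels (pitch 431.8/1024 = 0.4217 mm) at
#' 5 Hz. Source-detector and source-object distances are not stated for
#' the original rig; the defaults (1100 mm and 800 mm, magnification
#' 1.375) are documented assumptions.
#'
#' @param sid source-detector distance, mm.
#' @param sod nominal source-object distance, mm (object placement only).
#' @param image_size pixels, length 2 (nx, ny).
#' @param pixel_pitch mm per pixel, > 0.
#' @param frame_rate Hz.
#' @param source source position (lab, mm).
#' @param detector_centre centre of the detector plane (lab, mm).
#' @param u,v orthonormal in-plane detector axes (lab).
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(sid = 1100, sod = 800,
                                image_size = c(1024, 1024),
                                pixel_pitch = 431.8 / 1024, frame_rate = 5,
                                source = c(0, 0, 0),
                                detector_centre = c(0, 0, -sid),
                                u = c(1, 0, 0), v = c(0, 1, 0)) {
  stopifnot(pixel_pitch > 0, all(image_size > 0), length(image_size) == 2,
            frame_rate > 0, sod > 0)
  w <- detector_centre - source
  if (vnorm(w) < 1e-9) stop("source lies on the detector plane")
  structure(list(sid = vnorm(w), sod = sod,
                 image_size = as.integer(image_size),
                 pixel_pitch = pixel_pitch, frame_rate = frame_rate,
                 source = source, detector_centre = detector_centre,
                 u = vhat(u), v = vhat(v), w = vhat(w)),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat("<projection_geometry> ", x$image_size[1], "x", x$image_size[2],
      " px, pitch ", sprintf("%.4f", x$pixel_pitch), " mm, SID ",
      sprintf("%.0f", x$sid), " mm, SOD ", sprintf("%.0f", x$sod),
      " mm, ", x$frame_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Geometric magnification at the nominal object plane
#' @param geom a `projection_geometry`.
#' @return sid / sod.
#' @export
magnification <- function(geom) geom$sid / geom$sod

#' Perspective-project lab points to pixel coordinates
#' @param X n x 3 lab points (mm).
#' @param geom a `projection_geometry`.
#' @return list with `px` (n x 2 pixel coordinates, pixel centres at
#'   integers 1..nx / 1..ny) and `depth` (mm along the viewing axis).
#' @export
project_points <- function(X, geom) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 3)
  D <- sweep(X, 2, geom$source)
  depth <- as.numeric(D %*% geom$w)
  s <- geom$sid / depth
  Q <- D * s
  qc <- sweep(Q, 2, geom$detector_centre - geom$source)
  px <- cbind(as.numeric(qc %*% geom$u), as.numeric(qc %*% geom$v)) /
    geom$pixel_pitch
  px[, 1] <- px[, 1] + (geom$image_size[1] + 1) / 2
  px[, 2] <- px[, 2] + (geom$image_size[2] + 1) / 2
  list(px = px, depth = depth)
}

#' Render the binary silhouette of a posed mesh
#'
#' A pixel is foreground iff the ray from the source through the pixel
#' centre intersects the posed mesh (implemented by filling the projected
#' triangles). Deterministic.
#'
#' @param bone a `bone_model` or `knee_mesh`.
#' @param pose `rigid_pose` mapping bone-local to lab coordinates.
#' @param geom a `projection_geometry`.
#' @return Binary integer matrix indexed `[px, py]`, dims `image_size`.
#' @export
render_silhouette <- function(bone, pose, geom) {
  mesh <- if (inherits(bone, "bone_model")) bone$mesh else bone
  nx <- geom$image_size[1]
  ny <- geom$image_size[2]
  if (nrow(mesh$faces) == 0) return(matrix(0L, nx, ny))
  V <- pose_apply(pose, mesh$vertices)
  pr <- project_points(V, geom)
  if (any(pr$depth <= 1e-6) || any(pr$depth >= geom$sid - 1e-6))
    stop("geometry error: mesh must lie strictly between source and detector")
  raster_triangles_cpp(pr$px, mesh$faces, nx, ny)
}

#' Write a silhouette mask as PNG
#' @param mask binary integer matrix `[px, py]`.
#' @param path output PNG.
#' @export
write_silhouette_png <- function(mask, path) {
  # PNG rasters are [row, col] top-down; mask is [px, py] with py up
  img <- t(mask[, rev(seq_len(ncol(mask))), drop = FALSE])
  png::writePNG(img * 1.0, path)
  invisible(path)
}

#' Read a silhouette PNG back into a binary mask
#' @param path PNG file.
#' @return Binary integer matrix `[px, py]`.
#' @export
read_silhouette_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- t(img)
  m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' Write a projection-geometry sidecar JSON
#' @param geom a `projection_geometry`.
#' @param path output file.
#' @export
write_geometry_json <- function(geom, path) {
  jsonlite::write_json(unclass(geom), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a projection-geometry sidecar JSON
#' @param path file written by [write_geometry_json()].
#' @return A `projection_geometry`.
#' @export
read_geometry_json <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  projection_geometry(sid = g$sid, sod = g$sod, image_size = g$image_size,
                      pixel_pitch = g$pixel_pitch, frame_rate = g$frame_rate,
                      source = g$source, detector_centre = g$detector_centre,
                      u = g$u, v = g$v)
}
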