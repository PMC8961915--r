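#' Triangle meshes
#'
#' Minimal closed-triangle-mesh container used for the synthetic bones:
#' `vertices` is an n x 3 numeric matrix (mm) and `faces` an m x 3 integer
#' matrix of 1-based vertex indices with consistent outward winding.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix.
#' @return An object of class `knee_mesh`.
#' @export
knee_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "knee_mesh")
}

#' @export
print.knee_mesh <- function(x, ...) {
  cat("<knee_mesh> ", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces\n")
  invisible(x)
}

#' Is every mesh edge shared by exactly two faces?
#'
#' Closed, consistently oriented meshes (including disjoint unions of closed
#' components) satisfy this; open or inconsistently wound meshes do not.
#' @param mesh a `knee_mesh`.
#' @return logical.
#' @export
mesh_is_watertight <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0) return(FALSE)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key_dir <- paste(e[, 1], e[, 2])
  key_und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key_und)
  if (any(tab != 2)) return(FALSE)
  # consistent orientation: each directed edge must appear exactly once
  !any(duplicated(key_dir))
}

#' Apply a rigid pose to a mesh
#' @param mesh a `knee_mesh`.
#' @param pose a `rigid_pose`.
#' @return Transformed `knee_mesh`.
#' @export
mesh_transform <- function(mesh, pose) {
  knee_mesh(pose_apply(pose, mesh$vertices), mesh$faces)
}

#' Concatenate meshes
#' @param ... `knee_mesh` objects.
#' @return A single `knee_mesh` holding all components.
#' @export
mesh_combine <- function(...) {
  parts <- list(...)
  off <- 0L
  V <- NULL
  F <- NULL
  for (p in parts) {
    V <- rbind(V, p$vertices)
    F <- rbind(F, p$faces + off)
    off <- off + nrow(p$vertices)
  }
  knee_mesh(V, F)
}

#' Mirror a mesh across the x = 0 plane
#'
#' Face winding is flipped so outward orientation is preserved.
#' @param mesh a `knee_mesh`.
#' @return Mirrored `knee_mesh`.
#' @export
mesh_mirror_x <- function(mesh) {
  V <- mesh$vertices
  V[, 1] <- -V[, 1]
  knee_mesh(V, mesh$faces[, c(1, 3, 2), drop = FALSE])
}

#' Face centroids and areas
#' @param mesh a `knee_mesh`.
#' @return list with `centroids` (m x 3) and `areas` (length m, mm^2).
#' @export
mesh_face_info <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  cen <- (a + b + c_) / 3
  u <- b - a
  w <- c_ - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  list(centroids = cen, areas = 0.5 * sqrt(rowSums(cr^2)))
}

#' UV sphere mesh
#' @param centre length-3 centre (mm).
#' @param radius radius (mm).
#' @param n_theta longitudinal segments (>= 3).
#' @param n_phi latitudinal bands (>= 2).
#' @return Closed `knee_mesh`.
#' @export
mesh_sphere <- function(centre = c(0, 0, 0), radius = 1, n_theta = 24,
                        n_phi = 16) {
  stopifnot(radius > 0, n_theta >= 3, n_phi >= 2)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ph <- seq(0, pi, length.out = n_phi + 1)[-c(1, n_phi + 1)]
  ring <- function(p) cbind(radius * sin(p) * cos(th),
                            radius * sin(p) * sin(th),
                            rep(radius * cos(p), n_theta))
  V <- rbind(c(0, 0, radius), do.call(rbind, lapply(ph, ring)),
             c(0, 0, -radius))
  np <- nrow(V)
  idx <- function(i, j) 1L + (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  F <- NULL
  # top cap
  for (j in seq_len(n_theta))
    F <- rbind(F, c(1L, idx(1, j), idx(1, j + 1)))
  # bands
  nb <- length(ph)
  if (nb > 1) for (i in seq_len(nb - 1)) for (j in seq_len(n_theta)) {
    F <- rbind(F,
               c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  # bottom cap
  for (j in seq_len(n_theta))
    F <- rbind(F, c(np, idx(nb, j + 1), idx(nb, j)))
  m <- knee_mesh(sweep(V, 2, -centre), F)
  m
}

#' Capped cylinder mesh along the z axis
#' @param radius cylinder radius (mm).
#' @param z0,z1 bottom and top z (mm), `z0 < z1`.
#' @param centre_xy xy position of the axis.
#' @param n_theta circumferential segments.
#' @return Closed `knee_mesh`.
#' @export
mesh_cylinder <- function(radius = 1, z0 = 0, z1 = 1, centre_xy = c(0, 0),
                          n_theta = 24) {
  stopifnot(radius > 0, z1 > z0, n_theta >= 3)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  circ <- cbind(radius * cos(th) + centre_xy[1],
                radius * sin(th) + centre_xy[2])
  V <- rbind(cbind(circ, z0), cbind(circ, z1),
             c(centre_xy, z0), c(centre_xy, z1))
  cb <- nrow(V) - 1L
  ct <- nrow(V)
  nxt <- function(j) (j %% n_theta) + 1L
  F <- NULL
  for (j in seq_len(n_theta)) {
    jb <- j; jb2 <- nxt(j)
    jt <- j + n_theta; jt2 <- nxt(j) + n_theta
    F <- rbind(F,
               c(jb, jb2, jt2), c(jb, jt2, jt),       # side
               c(cb, jb2, jb),                        # bottom cap (faces -z)
               c(ct, jt, jt2))                        # top cap (faces +z)
  }
  knee_mesh(V, F)
}

#' Closed height-field slab
#'
#' A slab whose top surface is the graph of `top_fun(x, y)` over a regular
#' grid and whose bottom is flat at `z_bottom`; the perimeter is stitched so
#' the result is watertight. Used for the tibial plateau with its shallow
#' concave facets and intercondylar ridge.
#'
#' @param xs,ys strictly increasing grid coordinates (mm).
#' @param top_fun vectorized function `(x, y) -> z` of the top surface.
#' @param z_bottom z of the flat bottom; must lie below the top everywhere.
#' @return Closed `knee_mesh`.
#' @export
mesh_heightfield_slab <- function(xs, ys, top_fun, z_bottom) {
  nx <- length(xs)
  ny <- length(ys)
  stopifnot(nx >= 2, ny >= 2, all(diff(xs) > 0), all(diff(ys) > 0))
  g <- expand.grid(x = xs, y = ys)
  zt <- top_fun(g$x, g$y)
  if (any(zt <= z_bottom)) stop("top surface dips below the bottom plane")
  Vt <- cbind(g$x, g$y, zt)
  Vb <- cbind(g$x, g$y, z_bottom)
  V <- rbind(Vt, Vb)
  nt <- nrow(Vt)
  id <- function(i, j) (j - 1L) * nx + i          # top sheet index
  F <- NULL
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    v00 <- id(i, j); v10 <- id(i + 1, j)
    v01 <- id(i, j + 1); v11 <- id(i + 1, j + 1)
    # top faces wound +z (counter-clockwise seen from above)
    F <- rbind(F, c(v00, v10, v11), c(v00, v11, v01))
    # bottom faces wound -z
    F <- rbind(F, c(v00 + nt, v11 + nt, v10 + nt),
               c(v00 + nt, v01 + nt, v11 + nt))
  }
  # side walls around the perimeter (counter-clockwise loop seen from above)
  loop <- c(id(seq_len(nx), 1),
            id(nx, seq(2, ny)),
            id(seq(nx - 1, 1), ny),
            id(1, seq(ny - 1, 2)))
  nl <- length(loop)
  for (k in seq_len(nl)) {
    a <- loop[k]
    b <- loop[(k %% nl) + 1]
    F <- rbind(F, c(a, a + nt, b + nt), c(a, b + nt, b))
  }
  knee_mesh(V, F)
}

#' Write a mesh as ASCII STL
#' @param mesh a `knee_mesh`.
#' @param path output file.
#' @param name solid name recorded in the file.
#' @export
write_stl <- function(mesh, path, name = "mesh") {
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (k in seq_len(nrow(F))) {
    a <- V[F[k, 1], ]; b <- V[F[k, 2], ]; c_ <- V[F[k, 3], ]
    n <- vcross(b - a, c_ - a)
    nn <- vnorm(n)
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
                 sprintf("      vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
                 sprintf("      vertex %.9g %.9g %.9g", c_[1], c_[2], c_[3]),
                 "    endloop",
                 "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Read an ASCII STL file
#'
#' Duplicate vertices are merged exactly (string identity of coordinates),
#' so meshes written by [write_stl()] round-trip to an identical structure.
#' @param path STL file.
#' @return A `knee_mesh`.
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  if (nrow(xyz) %% 3 != 0) stop("malformed STL: vertex count not divisible by 3")
  key <- apply(xyz, 1, paste, collapse = " ")
  uk <- !duplicated(key)
  V <- xyz[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  F <- matrix(idx, ncol = 3, byrow = TRUE)
  knee_mesh(V, F)
}

#' Write a mesh as ASCII PLY
#' @param mesh a `knee_mesh`.
#' @param path output file.
#' @export
write_ply <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(V)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(F)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY file
#' @param path PLY file.
#' @return A `knee_mesh`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  hd_end <- match("end_header", lines)
  if (is.na(hd_end)) stop("malformed PLY: no end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vb <- lines[(hd_end + 1):(hd_end + nv)]
  fb <- lines[(hd_end + nv + 1):(hd_end + nv + nf)]
  V <- do.call(rbind, lapply(strsplit(vb, "\\s+"), function(p)
    as.numeric(p[1:3])))
  F <- do.call(rbind, lapply(strsplit(fb, "\\s+"), function(p)
    as.integer(p[2:4]) + 1L))
  knee_mesh(V, F)
}
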