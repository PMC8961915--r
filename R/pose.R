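#' Rigid poses (rotation + translation)
#'
#' A `rigid_pose` maps bone-local coordinates to lab coordinates (or, for
#' relative transforms, one frame into another): `x_lab = R %*% x + t`.
#' Rotations are 3x3 proper orthonormal matrices, translations in mm.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (mm).
#' @param frame_index optional frame number the pose belongs to.
#' @param cost optional registration cost attached to the pose.
#' @param converged optional convergence flag.
#' @return An object of class `rigid_pose`.
#' @export
rigid_pose <- function(R = diag(3), t = c(0, 0, 0), frame_index = NA_integer_,
                       cost = NA_real_, converged = NA) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("rotation must be proper orthonormal")
  structure(list(R = R, t = as.numeric(t), frame_index = frame_index,
                 cost = cost, converged = converged),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("<rigid_pose>  t = [", paste(sprintf("%.3f", x$t), collapse = ", "),
      "] mm\n", sep = "")
  if (!is.na(x$cost)) cat("  cost:", format(x$cost), " converged:",
                          x$converged, "\n")
  invisible(x)
}

#' Compose two rigid poses
#'
#' `pose_compose(p, q)` is the transform that first applies `q`, then `p`
#' (the usual matrix composition `p %*% q`).
#' @param p,q `rigid_pose` objects.
#' @return A `rigid_pose`.
#' @export
pose_compose <- function(p, q) {
  rigid_pose(p$R %*% q$R, as.numeric(p$R %*% q$t) + p$t)
}

#' Invert a rigid pose
#' @param p a `rigid_pose`.
#' @return The inverse `rigid_pose`.
#' @export
pose_invert <- function(p) {
  Rt <- t(p$R)
  rigid_pose(Rt, as.numeric(-Rt %*% p$t))
}

#' Apply a rigid pose to points
#' @param p a `rigid_pose`.
#' @param X n x 3 matrix of points (or a length-3 vector).
#' @return Transformed points, same shape as `X`.
#' @export
pose_apply <- function(p, X) {
  if (is.null(dim(X))) return(as.numeric(p$R %*% X) + p$t)
  sweep(X %*% t(p$R), 2, -p$t)
}

#' Rotation matrix from a rotation vector (Rodrigues)
#' @param v length-3 rotation vector, radians; its norm is the angle.
#' @return 3x3 rotation matrix.
#' @export
rotvec_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-14) return(diag(3))
  k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation vector from a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return length-3 rotation vector (radians).
#' @export
matrix_to_rotvec <- function(R) {
  ca <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  th <- acos(ca)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near 180 degrees: extract axis from R + I
    A <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(A), 0))
    i <- which.max(k)
    k <- A[, i] / k[i]
    return(th * k / sqrt(sum(k^2)))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th))
  th * ax
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

vnorm <- function(v) sqrt(sum(v^2))
vhat <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}
vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' A uniformly random rotation matrix
#' @param n ignored; one matrix is returned.
#' @return 3x3 rotation matrix drawn from the Haar measure.
#' @export
random_rotation <- function(n = 1) {
  # QR of a Gaussian matrix with sign fix
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
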