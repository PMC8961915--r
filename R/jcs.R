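#' Joint states in the Grood-Suntay convention
#'
#' Six degrees of freedom of the femur relative to the tibia: three
#' rotations (flexion, varus-valgus, internal-external) in degrees and three
#' translations (anterior-posterior, medial-lateral, inferior-superior) in
#' mm. Reporting signs: plus = posterior / medial / superior translation and
#' plus = varus / external rotation.
#'
#' Rotations follow the joint coordinate system: flexion about the femoral
#' body-fixed X axis (e1), axial rotation about the tibial body-fixed Z axis
#' (e3), varus-valgus as the angle between e1 and e3 minus 90 degrees.
#' Translations are resolved along the JCS axes (e1, floating e2, e3) by
#' default; `translations = "tibial"` resolves them along the tibial body
#' axes instead.
#'
#' @param flexion,varus,external rotations in degrees.
#' @param posterior,medial,superior translations in mm.
#' @return A one-row data.frame of class `joint_state`.
#' @export
joint_state <- function(flexion = 0, varus = 0, external = 0,
                        posterior = 0, medial = 0, superior = 0) {
  stopifnot(abs(varus) < 90)
  structure(data.frame(flexion = flexion, varus = varus, external = external,
                       posterior = posterior, medial = medial,
                       superior = superior),
            class = c("joint_state", "data.frame"))
}

JCS_DOFS <- c("flexion", "varus", "external", "posterior", "medial",
              "superior")

#' Relative transform of the femoral frame in the tibial frame
#'
#' `T = (tibia_pose o tibia_frame)^-1 o (femur_pose o femur_frame)`:
#' invariant to any common rigid motion applied to both lab poses.
#'
#' @param femur_pose,tibia_pose lab poses of the bones (`rigid_pose`).
#' @param femur_frame,tibia_frame bone-local `anatomical_frame`s.
#' @return A `rigid_pose` expressing the femoral frame in tibial-frame
#'   coordinates.
#' @export
relative_pose <- function(femur_pose, tibia_pose, femur_frame, tibia_frame) {
  pose_compose(pose_invert(pose_compose(tibia_pose, tibia_frame)),
               pose_compose(femur_pose, femur_frame))
}

#' Decompose a relative transform into the six JCS degrees of freedom
#'
#' @param T `rigid_pose` of the femoral frame in the tibial frame.
#' @param translations `"jcs"` (components along e1, floating e2, e3;
#'   default) or `"tibial"` (components along the tibial body axes).
#' @return A `joint_state`.
#' @export
decompose_jcs <- function(T, translations = c("jcs", "tibial")) {
  translations <- match.arg(translations)
  R <- T$R
  s <- -R[3, 1]                       # sin(varus)
  if (1 - abs(s) < 1e-9)
    stop("JCS singularity: varus-valgus at +/-90 degrees")
  b <- asin(s)
  a <- atan2(R[2, 1], R[1, 1])        # external rotation about tibial Z
  c_ <- atan2(R[3, 2], R[3, 3])       # flexion about femoral X
  e1 <- R[, 1]
  e3 <- c(0, 0, 1)
  e2 <- vhat(vcross(e3, e1))
  t <- T$t
  if (translations == "jcs") {
    # e1 and e3 are not mutually orthogonal away from zero varus-valgus:
    # recover the components in the (e1, e2, e3) basis exactly
    q <- solve(cbind(e1, e2, e3), t)
    ml <- q[1]
    ap <- q[2]
    is_ <- q[3]
  } else {
    ml <- t[1]
    ap <- t[2]
    is_ <- t[3]
  }
  joint_state(flexion = c_ * 180 / pi, varus = b * 180 / pi,
              external = a * 180 / pi,
              posterior = -ap, medial = ml, superior = is_)
}

#' Compose a relative transform from six JCS degrees of freedom
#'
#' Exact inverse of [decompose_jcs()].
#' @param js a `joint_state` (or named list with the six DOF).
#' @param translations see [decompose_jcs()].
#' @return A `rigid_pose`.
#' @export
compose_jcs <- function(js, translations = c("jcs", "tibial")) {
  translations <- match.arg(translations)
  stopifnot(abs(js$varus) < 90)
  a <- js$external * pi / 180
  b <- js$varus * pi / 180
  c_ <- js$flexion * pi / 180
  R <- rot_z(a) %*% rot_y(b) %*% rot_x(c_)
  e1 <- R[, 1]
  e3 <- c(0, 0, 1)
  e2 <- vhat(vcross(e3, e1))
  t <- if (translations == "jcs")
    js$medial * e1 - js$posterior * e2 + js$superior * e3
  else c(js$medial, -js$posterior, js$superior)
  rigid_pose(R, t)
}

#' Split a kneeling trial into flexion and extension phases
#'
#' The flexion phase runs from the first frame to the frame of maximum
#' flexion (inclusive); the extension phase from that frame to the end.
#' @param states data.frame with a `flexion` column, time-ordered.
#' @return list of integer index vectors `flexion` and `extension`.
#' @export
split_phases <- function(states) {
  apex <- which.max(states$flexion)
  list(flexion = seq_len(apex), extension = seq(apex, nrow(states)))
}

fit_curve <- function(time, value, smoothing) {
  if (smoothing == "interpolate" || length(unique(round(value, 12))) < 4) {
    f <- stats::splinefun(time, value, method = "fmm")
    return(f)
  }
  sp <- stats::smooth.spline(time, value, cv = FALSE)  # GCV
  function(t) stats::predict(sp, t)$y
}

#' Smooth a phase and resample it on the 5-degree flexion grid
#'
#' Each degree of freedom is fitted against time with a cubic smoothing
#' spline (smoothness chosen by generalized cross-validation by default);
#' the flexion-time curve is inverted within the phase to find the time at
#' which each grid angle is crossed, and all DOFs are evaluated at those
#' times. The per-subject maximum flexion (after smoothing) is appended as
#' its own grid row. Only interpolation is performed: grid angles outside
#' the observed flexion range are reported missing.
#'
#' @param states time-ordered data.frame with columns `time`, `flexion` and
#'   the value columns to resample (defaults to the six JCS DOFs present).
#' @param phase `"flexion"` or `"extension"`.
#' @param grid flexion grid angles in degrees (default 100, 105, ..., 155).
#' @param smoothing `"gcv"` (default) or `"interpolate"` (exact cubic
#'   interpolation, for noise-free data).
#' @param values character vector of columns to resample.
#' @return A data.frame of class `phase_series` with columns `angle`,
#'   `is_maxflex`, the value columns, and `missing`; attributes `phase` and
#'   `maxflex`.
#' @export
smooth_and_resample <- function(states, phase = c("flexion", "extension"),
                                grid = seq(100, 155, by = 5),
                                smoothing = c("gcv", "interpolate"),
                                values = intersect(JCS_DOFS, names(states))) {
  phase <- match.arg(phase)
  smoothing <- match.arg(smoothing)
  idx <- split_phases(states)[[phase]]
  win <- states[idx, , drop = FALSE]
  if (nrow(win) < 5) stop("need at least 5 frames within the phase")
  if (diff(range(win$flexion)) < 10)
    stop("flexion must span at least 10 degrees within the phase")
  flex_fun <- fit_curve(win$time, win$flexion, smoothing)
  tt <- seq(min(win$time), max(win$time), length.out = 512)
  fl <- flex_fun(tt)
  dfl <- diff(fl)
  mono_up <- all(dfl > -1e-8)
  mono_dn <- all(dfl < 1e-8)
  if (!mono_up && !mono_dn)
    stop("phase segmentation failed: smoothed flexion is not monotone ",
         "within the ", phase, " phase")
  maxflex <- max(fl)
  minflex <- min(fl)
  t_at <- function(a) {
    g <- function(t) flex_fun(t) - a
    stats::uniroot(g, range(win$time), tol = 1e-10)$root
  }
  angles <- c(grid, maxflex)
  is_mf <- c(rep(FALSE, length(grid)), TRUE)
  t_max <- tt[which.max(fl)]
  out <- data.frame(angle = angles, is_maxflex = is_mf)
  miss <- angles < minflex - 1e-9 | angles > maxflex + 1e-9
  times <- rep(NA_real_, length(angles))
  for (i in seq_along(angles)) {
    if (miss[i]) next
    times[i] <- if (is_mf[i]) t_max else t_at(angles[i])
  }
  for (v in values) {
    f <- fit_curve(win$time, win[[v]], smoothing)
    col <- rep(NA_real_, length(angles))
    col[!miss] <- f(times[!miss])
    out[[v]] <- col
  }
  out$missing <- miss
  structure(out, phase = phase, maxflex = maxflex,
            class = c("phase_series", "data.frame"))
}

#' @export
print.phase_series <- function(x, ...) {
  cat("<phase_series> phase:", attr(x, "phase"),
      " maxflex:", sprintf("%.1f", attr(x, "maxflex")), "deg\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Signed range of a degree of freedom over a phase
#'
#' Flexion phase: value at maximum flexion minus value at 100 degrees;
#' extension phase: value at 100 degrees minus value at maximum flexion
#' (so the sign follows the phase's direction of travel, as the printed
#' Range rows do).
#'
#' @param series a `phase_series` (or any data.frame with `angle`,
#'   `is_maxflex` and the value column).
#' @param dof name of the value column.
#' @param phase phase of the series; defaults to its `phase` attribute.
#' @return The signed range, with attribute `magnitude`.
#' @export
kinematic_range <- function(series, dof,
                            phase = attr(series, "phase") %||% "flexion") {
  if (!dof %in% names(series)) stop("no column '", dof, "' in series")
  v100 <- series[[dof]][!series$is_maxflex & series$angle == 100]
  vmax <- series[[dof]][series$is_maxflex]
  if (length(v100) != 1 || length(vmax) != 1 || is.na(v100) || is.na(vmax))
    stop("range undefined: endpoint at 100 degrees or maxflex is missing")
  r <- if (phase == "flexion") vmax - v100 else v100 - vmax
  structure(r, magnitude = abs(r))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
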