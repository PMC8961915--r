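#' Published per-angle summary tables for kneeling
#'
#' Per-angle cohort means and standard deviations of the six kinematic
#' degrees of freedom and the medial/lateral contact-point anterior
#' translation, on the 5-degree flexion grid from 100 degrees to maximum
#' flexion (cohort mean 161.3 degrees), for the flexion and extension
#' phases separately. These printed values are shipped as plain-text
#' fixtures and drive the shapes of the synthetic ground-truth
#' trajectories.
#'
#' @return A named list of data.frames: `ap_ie` (posterior translation mm,
#'   external rotation deg), `is_vv_ml` (superior translation mm, varus
#'   rotation deg, medial translation mm), `medial_cp` and `lateral_cp`
#'   (contact-point anterior translation, mm). Each has columns `angle`,
#'   `is_maxflex`, `n`, and `<measure>_{flex,ext}[_sd]`.
#' @export
kneeling_tables <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "kneelkin", mustWork = TRUE))
  list(ap_ie = rd("table1_ap_ie.csv"),
       is_vv_ml = rd("table2_is_vv_ml.csv"),
       medial_cp = rd("table3_medial_cp.csv"),
       lateral_cp = rd("table4_lateral_cp.csv"))
}

#' Piecewise-linear profile curve over flexion angle
#'
#' Builds the interpolant through per-angle values printed in a summary
#' table. The final row may be flagged `is_maxflex`; its angle is remapped
#' to the per-subject maximum flexion. Interpolation only: queries outside
#' the table's angle range are rejected.
#'
#' @param table data.frame with columns `angle` and `value`, and optionally
#'   `is_maxflex`; angles strictly increasing, at least 2 rows.
#' @param maxflex per-subject maximum flexion (degrees) onto which the
#'   `is_maxflex` row is mapped; `NULL` keeps the printed angle.
#' @return An object of class `profile_curve`: call it like a function, or
#'   use [eval_profile()].
#' @export
build_profile_from_table <- function(table, maxflex = NULL) {
  stopifnot(is.data.frame(table), nrow(table) >= 2,
            all(c("angle", "value") %in% names(table)))
  ang <- as.numeric(table$angle)
  val <- as.numeric(table$value)
  if (anyDuplicated(ang)) stop("duplicate angles in profile table")
  o <- order(ang)
  ang <- ang[o]
  val <- val[o]
  if (!is.null(table$is_maxflex) && any(table$is_maxflex) &&
      !is.null(maxflex)) {
    i <- which(table$is_maxflex[o])
    if (length(i) != 1 || i != length(ang))
      stop("the maxflex row must be the single last row")
    if (maxflex <= ang[i - 1])
      stop("maxflex must exceed the last fixed table angle")
    ang[i] <- maxflex
  }
  if (any(diff(ang) <= 0)) stop("table angles must be strictly increasing")
  f <- structure(list(angles = ang, values = val), class = "profile_curve")
  f
}

#' Evaluate a profile curve
#' @param curve a `profile_curve`.
#' @param angle flexion angles (degrees) within the curve's range.
#' @param extend if `TRUE`, queries outside the table's angle range are
#'   evaluated by extending the boundary segments linearly (used by the
#'   trajectory generator between 90 degrees and the table's first angle,
#'   so the curves are defined on the whole sweep without a kink at the
#'   first grid angle); if `FALSE` (default) such queries are rejected.
#' @return Interpolated values.
#' @export
eval_profile <- function(curve, angle, extend = FALSE) {
  a <- curve$angles
  v <- curve$values
  lo <- a[1]
  hi <- a[length(a)]
  if (!extend && any(angle < lo - 1e-9 | angle > hi + 1e-9))
    stop("angle outside the profile range [", lo, ", ", hi,
         "]: interpolation only")
  out <- stats::approx(a, v, xout = pmin(pmax(angle, lo), hi), rule = 2)$y
  if (extend) {
    n <- length(a)
    s_lo <- (v[2] - v[1]) / (a[2] - a[1])
    s_hi <- (v[n] - v[n - 1]) / (a[n] - a[n - 1])
    below <- angle < lo
    above <- angle > hi
    out[below] <- v[1] + s_lo * (angle[below] - lo)
    out[above] <- v[n] + s_hi * (angle[above] - hi)
  }
  out
}

#' Ground-truth trajectory profile of one subject
#'
#' Per-DOF piecewise-linear curves of value against flexion angle, separate
#' for the flexion and extension phases, plus the subject's maximum flexion
#' and total motion duration.
#'
#' @param curves nested list `curves[[phase]][[dof]]` of `profile_curve`s,
#'   phases `"flexion"` and `"extension"`, DOFs among `posterior`,
#'   `external`, `superior`, `varus`, `medial`.
#' @param maxflex subject maximum flexion (degrees).
#' @param duration_s total motion time in seconds, within [5, 10].
#' @return An object of class `trajectory_profile`.
#' @export
trajectory_profile <- function(curves, maxflex, duration_s = 7) {
  stopifnot(duration_s >= 5, duration_s <= 10, maxflex > 100)
  stopifnot(all(c("flexion", "extension") %in% names(curves)))
  structure(list(curves = curves, maxflex = maxflex,
                 duration_s = duration_s),
            class = "trajectory_profile")
}

#' Default profile shaped like the published per-angle means
#'
#' Builds both phases' curves for the five non-flexion DOFs from the
#' packaged summary tables, with the maxflex row mapped to the subject's
#' maximum flexion. The one typographically inconsistent printed value
#' (flexion-phase superior translation at 135 degrees, 10.4 among
#' neighbours near 40.4) is repaired to 40.4 before interpolation.
#'
#' @param maxflex subject maximum flexion (degrees), default the cohort
#'   mean 161.3.
#' @param duration_s total motion time (seconds), default 7.
#' @return A `trajectory_profile`.
#' @export
default_profile <- function(maxflex = 161.3, duration_s = 7) {
  tb <- kneeling_tables()
  t2 <- tb$is_vv_ml
  t2$superior_flex[t2$angle == 135 & !t2$is_maxflex] <- 40.4  # printed 10.4
  pick <- function(df, col) data.frame(angle = df$angle, value = df[[col]],
                                       is_maxflex = df$is_maxflex)
  curves <- list()
  for (ph in c("flex", "ext")) {
    cl <- list(
      posterior = build_profile_from_table(
        pick(tb$ap_ie, paste0("posterior_", ph)), maxflex),
      external = build_profile_from_table(
        pick(tb$ap_ie, paste0("external_", ph)), maxflex),
      superior = build_profile_from_table(
        pick(t2, paste0("superior_", ph)), maxflex),
      varus = build_profile_from_table(
        pick(t2, paste0("varus_", ph)), maxflex),
      medial = build_profile_from_table(
        pick(t2, paste0("medial_", ph)), maxflex))
    curves[[if (ph == "flex") "flexion" else "extension"]] <- cl
  }
  trajectory_profile(curves, maxflex, duration_s)
}

#' Default per-DOF between-subject standard deviations
#'
#' One constant offset per subject and DOF is drawn with these SDs; they
#' default to the mean of the printed flexion-phase per-angle SD columns.
#' @return Named numeric vector (mm or degrees).
#' @export
default_subject_sd <- function() {
  tb <- kneeling_tables()
  c(posterior = mean(tb$ap_ie$posterior_flex_sd),
    external = mean(tb$ap_ie$external_flex_sd),
    superior = mean(tb$is_vv_ml$superior_flex_sd),
    varus = mean(tb$is_vv_ml$varus_flex_sd),
    medial = mean(tb$is_vv_ml$medial_flex_sd))
}
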