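#' Pipeline configuration
#'
#' Everything [run_pipeline()] needs for a simulated cohort study:
#' cohort size, seeds, projection geometry, whether poses come from the
#' ground truth or from silhouette registration, and which stages run.
#'
#' @param n_subjects cohort size (>= 1).
#' @param seed master seed; subject seeds are derived from it.
#' @param registration `"truth"` (use the generator's poses) or
#'   `"silhouette"` (render each frame and run 2D/3D registration).
#' @param contact run the contact-point stage.
#' @param stats run the phase-comparison stage.
#' @param subject_sd per-DOF between-subject offset SDs (see
#'   [default_subject_sd()]); use 0 for noise-free subjects on the mean
#'   curves.
#' @param duration_s motion duration per subject (s).
#' @param geom a `projection_geometry`.
#' @param grid flexion grid (degrees).
#' @param smoothing spline smoothing mode, see [smooth_and_resample()].
#' @param d_max threshold search bound (mm).
#' @param reg_control registration settings, see [reg_control()].
#' @param out_dir optional output directory for CSVs and the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 15, seed = 1L,
                            registration = c("truth", "silhouette"),
                            contact = TRUE, stats = TRUE,
                            subject_sd = default_subject_sd(),
                            duration_s = 7,
                            geom = projection_geometry(),
                            grid = seq(100, 155, by = 5),
                            smoothing = "gcv", d_max = 10,
                            reg_control = kneelkin::reg_control(),
                            out_dir = NULL) {
  registration <- match.arg(registration)
  stopifnot(n_subjects >= 1, all(diff(grid) > 0), grid[1] < 180,
            seed == as.integer(seed))
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 registration = registration, contact = contact,
                 stats = stats, subject_sd = subject_sd,
                 duration_s = duration_s, geom = geom, grid = grid,
                 smoothing = smoothing, d_max = d_max,
                 reg_control = reg_control, out_dir = out_dir),
            class = "pipeline_config")
}

subject_relative_poses <- function(subj, registration, control, seed) {
  n <- nrow(subj$truth)
  ff <- bone_frame(subj$bones$femur)
  tf <- bone_frame(subj$bones$tibia)
  if (registration == "truth") {
    poses <- subj$poses
  } else {
    geom <- subj$geom
    obs_for <- function(bone) function(i) silhouette_observation(
      render_subject_frame(subj, i, bone), geom,
      time_s = subj$truth$time[i])
    fem <- track_sequence(subj$bones$femur, obs_for("femur"),
                          subj$poses[[1]]$femur, n_frames = n,
                          control = control, seed = seed)
    tib <- track_sequence(subj$bones$tibia, obs_for("tibia"),
                          subj$poses[[1]]$tibia, n_frames = n,
                          control = control, seed = seed + n)
    poses <- lapply(seq_len(n), function(i)
      list(femur = fem[[i]], tibia = tib[[i]]))
  }
  lapply(seq_len(n), function(i)
    relative_pose(poses[[i]]$femur, poses[[i]]$tibia, ff, tf))
}

#' Run the full kneeling-analysis pipeline on a simulated cohort
#'
#' Generates `n_subjects` synthetic subjects, obtains per-frame relative
#' poses (ground truth or silhouette registration), decomposes them into
#' the six joint-coordinate-system DOFs, smooths and resamples each phase
#' on the flexion grid, optionally computes contact points and their
#' series, and summarizes flexion-vs-extension statistics. Deterministic
#' given the configuration's seeds; with `out_dir` set, all tables are
#' written as CSV together with a manifest recording the configuration
#' hash.
#'
#' @param config a `pipeline_config`.
#' @return An object of class `kneel_study`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n_subjects < 1) stop("validation error: empty subject list")
  subjects <- list()
  kin <- list(flexion = list(), extension = list())
  cps <- list(flexion = list(), extension = list())
  thresholds <- numeric(0)
  for (s in seq_len(config$n_subjects)) {
    subj <- synthetic_subject(seed = config$seed + s,
                              geom = config$geom,
                              duration_s = config$duration_s,
                              subject_sd = config$subject_sd)
    rel <- subject_relative_poses(subj, config$registration,
                                  config$reg_control,
                                  seed = config$seed + 1000L * s)
    states <- do.call(rbind, lapply(rel, function(T)
      decompose_jcs(T)))
    states <- cbind(time = subj$truth$time, states)
    for (ph in c("flexion", "extension"))
      kin[[ph]][[subj$id]] <- smooth_and_resample(
        states, phase = ph, grid = config$grid,
        smoothing = config$smoothing)
    if (config$contact) {
      maps <- lapply(rel, function(T)
        proximity_map(subj$bones$femur, subj$bones$tibia, T))
      d <- withCallingHandlers(
        select_threshold(maps, d_max = config$d_max),
        warning = function(w) invokeRestart("muffleWarning"))
      thresholds[subj$id] <- d
      cp <- do.call(rbind, lapply(maps, function(m) {
        p <- contact_points(m, d)
        data.frame(medial_y = p$medial$y, lateral_y = p$lateral$y,
                   medial_area = p$medial$area,
                   lateral_area = p$lateral$area)
      }))
      cpf <- cbind(time = subj$truth$time, cp)
      for (ph in c("flexion", "extension"))
        cps[[ph]][[subj$id]] <- cp_series(cpf, states, phase = ph,
                                          grid = config$grid,
                                          smoothing = config$smoothing)
    }
    subj$images <- NULL
    subjects[[subj$id]] <- list(id = subj$id, seed = subj$seed,
                                maxflex = subj$maxflex, truth = subj$truth,
                                states = states)
  }
  tables <- list()
  stats_out <- list()
  dofs <- c("posterior", "external", "superior", "varus", "medial")
  for (d in dofs)
    tables[[d]] <- summarize_tables(kin$flexion, kin$extension, d)
  if (config$contact && length(cps$flexion)) {
    tables$medial_cp <- summarize_tables(cps$flexion, cps$extension,
                                         "medial_y",
                                         diff_from = list(flex = 140,
                                                          ext = 125))
    tables$lateral_cp <- summarize_tables(cps$flexion, cps$extension,
                                          "lateral_y",
                                          diff_from = list(flex = 100,
                                                           ext = "maxflex"))
  }
  if (config$stats && config$n_subjects >= 3) {
    measures <- c(dofs, if (config$contact) c("medial_y", "lateral_y"))
    for (m in measures) {
      src <- if (m %in% dofs) kin else cps
      D <- phase_difference_matrix(src$flexion, src$extension, m)
      stats_out[[m]] <- tryCatch(overall_phase_difference(D),
                                 error = function(e) NULL)
    }
  }
  study <- structure(list(config = config, subjects = subjects,
                          kinematics = kin, contact_points = cps,
                          thresholds = thresholds, tables = tables,
                          overall = stats_out),
                     class = "kneel_study")
  if (!is.null(config$out_dir)) write_study(study, config$out_dir)
  study
}

#' Subject-by-angle flexion-minus-extension difference matrix
#' @param flex_series,ext_series per-subject `phase_series` lists.
#' @param value value column.
#' @return subjects x grid-angles matrix (grid rows only, no maxflex row).
#' @export
phase_difference_matrix <- function(flex_series, ext_series, value) {
  n <- length(flex_series)
  grid <- flex_series[[1]]$angle[!flex_series[[1]]$is_maxflex]
  D <- matrix(NA_real_, n, length(grid))
  for (s in seq_len(n)) {
    f <- flex_series[[s]]
    e <- ext_series[[s]]
    D[s, ] <- f[[value]][!f$is_maxflex] - e[[value]][!e$is_maxflex]
  }
  D
}

#' Write a study's tables and manifest to a directory
#' @param study a `kneel_study`.
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(study$tables))
    utils::write.csv(as.data.frame(study$tables[[nm]]),
                     file.path(dir, paste0("table_", nm, ".csv")),
                     row.names = FALSE)
  kin_rows <- list()
  for (ph in names(study$kinematics))
    for (id in names(study$kinematics[[ph]])) {
      s <- as.data.frame(study$kinematics[[ph]][[id]])
      s$subject <- id
      s$phase <- ph
      kin_rows[[paste(ph, id)]] <- s
    }
  utils::write.csv(do.call(rbind, kin_rows),
                   file.path(dir, "kinematics.csv"), row.names = FALSE)
  ov <- lapply(study$overall, function(o)
    if (is.null(o)) NULL else list(estimate = o$estimate, ci = o$ci))
  manifest <- list(
    config_hash = config_hash(study$config),
    n_subjects = study$config$n_subjects,
    seed = study$config$seed,
    registration = study$config$registration,
    thresholds = as.list(study$thresholds),
    overall = ov)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

config_hash <- function(config) {
  x <- config
  x$out_dir <- NULL
  s <- paste(utils::capture.output(utils::str(x, digits.d = 12)),
             collapse = "\n")
  # small stable polynomial hash, no extra dependencies
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2^31
  sprintf("%08x", h)
}

#' @export
print.kneel_study <- function(x, ...) {
  cat("<kneel_study>", x$config$n_subjects, "subjects, poses from",
      x$config$registration, "\n")
  if (length(x$thresholds))
    cat("  contact thresholds (mm):",
        paste(sprintf("%.1f", x$thresholds), collapse = " "), "\n")
  for (nm in names(x$tables)) {
    r <- attr(x$tables[[nm]], "range")
    cat(sprintf("  %-10s range: flexion %6.1f  extension %6.1f\n",
                nm, r[["flex"]], r[["ext"]]))
  }
  invisible(x)
}

#' @export
summary.kneel_study <- function(object, ...) {
  print(object)
  for (m in names(object$overall)) {
    o <- object$overall[[m]]
    if (is.null(o)) next
    cat(sprintf("  overall %s difference: %.2f (95%% CI %.2f to %.2f)\n",
                m, o$estimate, o$ci[1], o$ci[2]))
  }
  invisible(object)
}
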