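#' Silhouette observation
#'
#' One binary fluoroscopic silhouette with its projection geometry.
#' @param image binary integer matrix `[px, py]`.
#' @param geom a `projection_geometry` whose `image_size` matches.
#' @param time_s acquisition time (s).
#' @return An object of class `silhouette_observation`.
#' @export
silhouette_observation <- function(image, geom, time_s = NA_real_) {
  if (!all(dim(image) == geom$image_size))
    stop("image size does not match the projection geometry")
  if (!any(image != 0)) stop("observation has empty foreground")
  structure(list(image = image, geom = geom, time_s = time_s),
            class = "silhouette_observation")
}

#' Silhouette mismatch cost
#'
#' `cost = w_iou * (1 - IoU) + w_contour * mean symmetric contour distance`
#' (px). The contour distance is the average of the two directed mean
#' nearest-boundary-pixel distances. Zero iff the masks are identical;
#' symmetric in its arguments. The default weights make both terms O(1)
#' near convergence.
#'
#' @param observed,rendered equal-size binary masks.
#' @param w_iou,w_contour term weights (defaults 1 and 0.5 per px; the
#'   contour term is the smooth, informative one near convergence).
#' @return Non-negative scalar with attributes `iou` and `contour_dist`.
#' @export
silhouette_cost <- function(observed, rendered, w_iou = 1, w_contour = 0.5) {
  if (!all(dim(observed) == dim(rendered)))
    stop("mask size mismatch")
  if (!any(observed != 0)) stop("observed mask is empty")
  ov <- mask_overlap_cpp(observed, rendered)
  structure(w_iou * (1 - ov$iou) + w_contour * ov$contour_dist,
            iou = ov$iou, contour_dist = ov$contour_dist)
}

#' Optimizer settings for silhouette registration
#'
#' Derivative-free simplex (Nelder-Mead) with restarts. Rotations are
#' parameterized as rotation-vector increments about the current estimate,
#' which avoids Euler singularities.
#'
#' @param max_eval function-evaluation budget per restart.
#' @param restarts number of simplex restarts (recentred, shrinking steps).
#' @param reltol relative convergence tolerance on the cost.
#' @param step_t initial translation simplex step, mm.
#' @param step_r initial rotation simplex step, degrees.
#' @param depth_scale relative simplex step along the viewing axis (depth
#'   is weakly constrained in a single-plane view).
#' @param multi_start number of seeded jittered initializations tried when
#'   the initial pose does not overlap the observation.
#' @param w_iou,w_contour cost weights, see [silhouette_cost()].
#' @param escape_cost when the best cost after the restart cycle exceeds
#'   this value, the solution is treated as a depth-rotation local
#'   minimum and deterministic escape restarts are run from viewing-axis
#'   offsets.
#' @param escape_offsets depth offsets (mm, along the viewing axis) tried
#'   by the escape restarts.
#' @return list of control settings.
#' @export
reg_control <- function(max_eval = 500, restarts = 3, reltol = 1e-3,
                        step_t = 1, step_r = 1, depth_scale = 3,
                        multi_start = 8, w_iou = 1, w_contour = 0.5,
                        escape_cost = 0.1,
                        escape_offsets = c(-6, -3, 3, 6)) {
  list(max_eval = max_eval, restarts = restarts, reltol = reltol,
       step_t = step_t, step_r = step_r, depth_scale = depth_scale,
       multi_start = multi_start, w_iou = w_iou, w_contour = w_contour,
       escape_cost = escape_cost, escape_offsets = escape_offsets)
}

reg_cost_fun <- function(mesh, obs, geom, control) {
  fg <- which(obs != 0)
  nx <- nrow(obs)
  ix <- (fg - 1L) %% nx + 1L
  iy <- (fg - 1L) %/% nx + 1L
  bounds <- c(min(ix), max(ix), min(iy), max(iy))
  function(R, t) {
    V <- sweep(mesh$vertices %*% t(R), 2, -t)
    pr <- project_points(V, geom)
    if (any(pr$depth <= 1e-6) || any(pr$depth >= geom$sid - 1e-6))
      return(1e6)
    render_cost_cpp(pr$px, mesh$faces, obs, bounds[1], bounds[2],
                    bounds[3], bounds[4], control$w_iou, control$w_contour)
  }
}

#' Register one bone to one silhouette frame
#'
#' Recovers the six-DOF pose minimizing [silhouette_cost()] between the
#' rendered model silhouette and the observed one, by Nelder-Mead over
#' (translation, rotation-vector increment) with restarts. Deterministic
#' given the initialization and seed.
#'
#' @param bone a `bone_model` (or `knee_mesh`).
#' @param obs a `silhouette_observation`.
#' @param init initial `rigid_pose`; must render to a silhouette
#'   overlapping the observation, else seeded multi-start jitters are
#'   tried.
#' @param control see [reg_control()].
#' @param seed seed for multi-start jitters.
#' @return The recovered `rigid_pose` with `cost` and `converged` set.
#' @export
register_frame <- function(bone, obs, init, control = reg_control(),
                           seed = 1L) {
  mesh <- if (inherits(bone, "bone_model")) bone$mesh else bone
  geom <- obs$geom
  fcost <- reg_cost_fun(mesh, obs$image, geom, control)
  c0 <- fcost(init$R, init$t)
  if (c0 == 0)
    return(rigid_pose(init$R, init$t, frame_index = init$frame_index,
                      cost = 0, converged = TRUE))
  iou0 <- attr(silhouette_cost(obs$image,
                               render_silhouette(mesh, init, geom),
                               control$w_iou, control$w_contour), "iou")
  R0 <- init$R
  t0 <- init$t
  if (iou0 <= 0) {
    # seeded multi-start around the initialization
    set.seed(seed)
    found <- FALSE
    for (k in seq_len(control$multi_start)) {
      tj <- init$t + stats::rnorm(3, 0, 10)
      Rj <- rotvec_to_matrix(stats::rnorm(3, 0, 5 * pi / 180)) %*% init$R
      rj <- render_silhouette(mesh, rigid_pose(Rj, tj), geom)
      if (sum(rj & obs$image) > 0) {
        R0 <- Rj
        t0 <- tj
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("registration failure: no silhouette overlap after multi-start")
  }
  one_restart <- function(R0, t0, shrink) {
    obj <- function(p) {
      Rr <- rotvec_to_matrix(p[4:6] * pi / 180) %*% R0
      fcost(Rr, t0 + p[1:3])
    }
    ps <- c(rep(control$step_t, 3), rep(control$step_r, 3)) * shrink
    ps[3] <- ps[3] * control$depth_scale  # viewing axis: weak constraint
    fit <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                        control = list(maxit = control$max_eval,
                                       reltol = control$reltol,
                                       parscale = ps * 10))
    list(R = rotvec_to_matrix(fit$par[4:6] * pi / 180) %*% R0,
         t = t0 + fit$par[1:3], value = fit$value)
  }
  run_cycle <- function(R0, t0, best) {
    shrink <- 1
    for (r in seq_len(control$restarts)) {
      fit <- one_restart(R0, t0, shrink)
      if (fit$value <= best + 1e-12) {
        best <- fit$value
        t0 <- fit$t
        R0 <- fit$R
      }
      shrink <- shrink * 0.4
      if (best < 1e-9) break
    }
    list(R = R0, t = t0, value = best)
  }
  sol <- run_cycle(R0, t0, fcost(R0, t0))
  if (sol$value > control$escape_cost && length(control$escape_offsets)) {
    # likely stuck in the depth-rotation ambiguity valley: retry from
    # deterministic offsets along the viewing axis and keep the best
    w <- geom$w
    for (dz in control$escape_offsets) {
      t_try <- sol$t + dz * w
      cand <- run_cycle(sol$R, t_try, fcost(sol$R, t_try))
      if (cand$value < sol$value) sol <- cand
      if (sol$value <= control$escape_cost) break
    }
  }
  rigid_pose(sol$R, sol$t, frame_index = init$frame_index, cost = sol$value,
             converged = TRUE)
}

#' Track a bone through a time-ordered silhouette stack
#'
#' Frame k is initialized from the recovered pose of frame k-1 (frame 1
#' from `init0`). Per-frame registration failures are flagged, not
#' silently dropped.
#'
#' @param bone a `bone_model`.
#' @param obs_stack list of `silhouette_observation`s, or a function
#'   `(i) -> silhouette_observation` rendered on demand.
#' @param init0 initial pose for the first frame.
#' @param n_frames number of frames (required when `obs_stack` is a
#'   function).
#' @param control see [reg_control()].
#' @param seed seed passed to per-frame registration.
#' @return list of recovered `rigid_pose`s; failed frames carry
#'   `converged = FALSE` and an `error` attribute.
#' @export
track_sequence <- function(bone, obs_stack, init0,
                           n_frames = length(obs_stack),
                           control = reg_control(), seed = 1L) {
  get_obs <- if (is.function(obs_stack)) obs_stack
  else function(i) obs_stack[[i]]
  out <- vector("list", n_frames)
  prev <- init0
  for (i in seq_len(n_frames)) {
    prev$frame_index <- i
    res <- tryCatch(register_frame(bone, get_obs(i), prev, control,
                                   seed = seed + i),
                    error = function(e) e)
    if (inherits(res, "error")) {
      p <- prev
      p$converged <- FALSE
      p$cost <- NA_real_
      attr(p, "error") <- conditionMessage(res)
      out[[i]] <- p
    } else {
      out[[i]] <- res
      prev <- res
    }
  }
  out
}

#' Write a pose sequence as CSV
#' @param poses list of `rigid_pose`s.
#' @param path output CSV (frame, rotation-vector, translation, cost,
#'   converged).
#' @export
write_poses_csv <- function(poses, path) {
  rows <- lapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    rv <- matrix_to_rotvec(p$R)
    data.frame(frame = i, rx = rv[1], ry = rv[2], rz = rv[3],
               tx = p$t[1], ty = p$t[2], tz = p$t[3],
               cost = p$cost, converged = p$converged)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
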