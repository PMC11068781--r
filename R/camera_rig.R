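#' Build a synthetic multi-camera goal rig
#'
#' Constructs pinhole cameras (focal length in pixels, principal point at
#' the image centre, look-at orientation) and expresses each as an exact
#' 11-coefficient DLT model, together with a control-point set laid out on
#' the goal frame: the official 7.32 m x 2.44 m face plus back-frame depth
#' points so the set spans a volume. The `"paper3cam"` preset places one
#' camera in front of the goal behind the penalty mark and two lateral
#' cameras with a diagonal view.
#'
#' @param layout `"paper3cam"`, or a data.frame with columns
#'   `camera_id, x, y, z` (camera positions, m) and optionally `f_px`.
#' @param f_px focal length (px) for preset/defaulted cameras. Default 1100.
#' @param image_size image width and height (px). Default c(1920, 1080).
#' @param target look-at point (m). Default c(0, 0, 1.2).
#' @param goal_depth depth of the back frame behind the goal line (m).
#'   Default 1.5.
#' @return list with `cameras` (list of [dlt_camera()]), `control_points`
#'   (list: `ids`, `xyz`, `uv_per_camera`) and `layout`.
#' @export
make_camera_rig <- function(layout = "paper3cam", f_px = 1100,
                            image_size = c(1920, 1080),
                            target = c(0, 0, 1.2), goal_depth = 1.5) {
  if (is.character(layout)) {
    layout <- match.arg(layout, "paper3cam")
    layout <- data.frame(
      camera_id = c("central", "lateral_left", "lateral_right"),
      x = c(14, 8, 8), y = c(0, 7, -7), z = c(1.6, 1.7, 1.7))
  }
  if (!all(c("camera_id", "x", "y", "z") %in% names(layout)))
    stop("a custom layout needs columns camera_id, x, y, z")
  if (nrow(layout) < 2L)
    stop(sprintf("a rig needs >= 2 camera poses, got %d", nrow(layout)))
  if (is.null(layout$f_px)) layout$f_px <- f_px

  hw <- 7.32 / 2; hh <- 2.44; gd <- -goal_depth
  xyz <- rbind(
    c(0, -hw, 0), c(0, -hw, hh), c(0, hw, 0), c(0, hw, hh), c(0, 0, hh),
    c(gd, -hw, 0), c(gd, -hw, hh), c(gd, hw, 0), c(gd, hw, hh),
    c(gd, 0, hh), c(gd, 0, 0))
  ids <- c("post_r_base", "post_r_top", "post_l_base", "post_l_top",
           "crossbar_mid", "back_r_base", "back_r_top", "back_l_base",
           "back_l_top", "back_bar_mid", "back_ground_mid")
  # working volume: where the goalkeeper moves, plus the goal frame itself
  wv <- as.matrix(expand.grid(x = c(gd, 2.2), y = c(-hw, hw), z = c(0, 2.5)))

  cams <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    C <- as.numeric(layout[i, c("x", "y", "z")])
    zc <- target - C; zc <- zc / sqrt(sum(zc^2))       # viewing direction
    xc <- c(zc[2L], -zc[1L], 0)                        # cross(zc, up = z)
    xc <- xc / sqrt(sum(xc^2))
    yc <- c(zc[2L] * xc[3L] - zc[3L] * xc[2L],         # cross(zc, xc)
            zc[3L] * xc[1L] - zc[1L] * xc[3L],
            zc[1L] * xc[2L] - zc[2L] * xc[1L])
    K <- rbind(c(layout$f_px[i], 0, image_size[1L] / 2),
               c(0, layout$f_px[i], image_size[2L] / 2),
               c(0, 0, 1))
    R <- rbind(xc, yc, zc)
    P <- K %*% cbind(R, -R %*% C)
    if (P[3L, 4L] == 0) stop("camera at the world origin: DLT undefined")
    Lfull <- P / P[3L, 4L]
    cam <- dlt_camera(layout$camera_id[i], c(t(Lfull))[1:11])
    den_wv <- wv %*% cam$L[9:11] + 1
    if (any(den_wv <= 0))
      stop_divekin(sprintf("camera '%s' sits behind the working volume",
                           layout$camera_id[i]), "divekin_behind_camera")
    cams[[i]] <- cam
  }
  uv <- lapply(cams, function(cam) dlt_project(cam, xyz))
  list(cameras = cams,
       control_points = list(ids = ids, xyz = xyz, uv_per_camera = uv),
       layout = layout)
}

#' Render a 3D trajectory into per-camera keypoint streams
#'
#' Projects every landmark through each camera, adds i.i.d. Gaussian pixel
#' noise, and emits dropouts as confidence-0 keypoints (zeroed
#' coordinates, the pose-estimator convention for undetected points).
#' Landmarks behind a camera are flagged and emitted as dropouts.
#' Deterministic given `seed`. The output is readable by
#' [read_pose_sequence()] after [write_pose_sequence()].
#'
#' @param traj a [trajectory3d()].
#' @param cameras list of [dlt_camera()].
#' @param noise_px image-noise SD (px). Default 0.
#' @param dropout_rate per-keypoint missing probability in [0, 1).
#'   Default 0.
#' @param seed RNG seed. Default 1.
#' @return list of [pose_sequence()], one per camera.
#' @export
render_views <- function(traj, cameras, noise_px = 0, dropout_rate = 0,
                         seed = 1L) {
  stopifnot(inherits(traj, "trajectory3d"))
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must lie in [0, 1)")
  n <- dim(traj$positions)[1L]
  pts <- matrix(aperm(traj$positions, c(1L, 2L, 3L)), n * N_KEYPOINTS, 3L)
  set.seed(seed)
  out <- vector("list", length(cameras))
  for (i in seq_along(cameras)) {
    uv <- dlt_project(cameras[[i]], pts, on_behind = "na")
    u <- matrix(uv[, 1L], n, N_KEYPOINTS)
    v <- matrix(uv[, 2L], n, N_KEYPOINTS)
    if (noise_px > 0) {
      u <- u + matrix(stats::rnorm(n * N_KEYPOINTS, 0, noise_px), n)
      v <- v + matrix(stats::rnorm(n * N_KEYPOINTS, 0, noise_px), n)
    }
    conf <- matrix(stats::runif(n * N_KEYPOINTS, 0.55, 0.95), n)
    drop <- matrix(stats::runif(n * N_KEYPOINTS) < dropout_rate, n) | is.na(u)
    conf[drop] <- 0
    u[drop] <- 0; v[drop] <- 0
    out[[i]] <- pose_sequence(cameras[[i]]$camera_id, traj$fs, u, v, conf,
                              traj$frame_index)
  }
  out
}
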