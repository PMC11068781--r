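#' Construct a 3D landmark trajectory
#'
#' @param positions numeric array, frames x 25 x 3, world coordinates (m)
#'   of the BODY_25 landmarks in the field frame (X anteroposterior,
#'   Y mediolateral, Z vertical).
#' @param fs sampling rate (Hz).
#' @param frame_index 0-based frame indices.
#' @return an object of class `trajectory3d`.
#' @export
trajectory3d <- function(positions, fs, frame_index = seq_len(dim(positions)[1L]) - 1L) {
  stopifnot(length(dim(positions)) == 3L,
            dim(positions)[2L] == N_KEYPOINTS, dim(positions)[3L] == 3L,
            fs > 0)
  structure(list(positions = positions, fs = fs,
                 frame_index = as.integer(frame_index)),
            class = "trajectory3d")
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("<trajectory3d> %d frames x 25 landmarks @ %g Hz\n",
              dim(x$positions)[1L], x$fs))
  invisible(x)
}

#' Load the default anthropometric segment table
#'
#' Fourteen body segments (head, trunk, and left/right upper arm, forearm,
#' hand, thigh, shank, foot), each defined by a proximal and a distal
#' BODY_25 landmark, a body-mass fraction, and the segment-CM position as
#' a fraction of the proximal-to-distal vector. Values follow the de
#' Leva-style standardized parameters used with the segmental CM method.
#' The head row uses the neck-to-nose axis as a proxy for the head
#' longitudinal axis, the trunk spans neck to mid-hip, and hands are
#' treated as point masses at the wrist, since BODY_25 provides no
#' segment endpoints beyond the wrist. The table is a plain CSV and fully
#' user-replaceable; any replacement is validated by
#' [validate_anthropometric_table()].
#'
#' @return data.frame with columns segment, proximal_id, distal_id,
#'   mass_fraction, cm_ratio.
#' @export
default_anthropometric_table <- function() {
  path <- system.file("extdata", "anthropometric_segments.csv",
                      package = "divekin", mustWork = TRUE)
  validate_anthropometric_table(utils::read.csv(path))
}

#' Validate an anthropometric segment table
#'
#' Checks the invariants required by the segmental CM method: 14 segment
#' rows, mass fractions summing to 1 within 1e-9, CM ratios in [0, 1],
#' and landmark ids within the BODY_25 range 0-24.
#'
#' @param table candidate table (see [default_anthropometric_table()]).
#' @return the table, invisibly validated (returned unchanged).
#' @export
validate_anthropometric_table <- function(table) {
  need <- c("segment", "proximal_id", "distal_id", "mass_fraction", "cm_ratio")
  if (!all(need %in% names(table)))
    stop(sprintf("anthropometric table must have columns %s", paste(need, collapse = ", ")))
  if (nrow(table) != 14L)
    stop(sprintf("anthropometric table must define 14 segments, got %d", nrow(table)))
  if (abs(sum(table$mass_fraction) - 1) > 1e-9)
    stop(sprintf("segment mass fractions must sum to 1 (got %.12f)", sum(table$mass_fraction)))
  if (any(table$cm_ratio < 0 | table$cm_ratio > 1))
    stop("every cm_ratio must lie in [0, 1]")
  ids <- c(table$proximal_id, table$distal_id)
  if (any(ids < 0L | ids > 24L)) stop("landmark ids must lie in 0-24")
  table
}

## collapse the segment table to a 25-long landmark weight vector:
## whole-body CM = positions %*% w on each axis
cm_landmark_weights <- function(table) {
  w <- numeric(N_KEYPOINTS)
  for (s in seq_len(nrow(table))) {
    p <- lm_col(table$proximal_id[s]); d <- lm_col(table$distal_id[s])
    r <- table$cm_ratio[s]; mf <- table$mass_fraction[s]
    w[p] <- w[p] + mf * (1 - r)
    w[d] <- w[d] + mf * r
  }
  w
}

#' Whole-body centre of mass by the segmental method
#'
#' Per frame, each segment's CM is placed at
#' `proximal + cm_ratio * (distal - proximal)` and the whole-body CM is
#' the mass-fraction-weighted sum over the 14 segments. `body_mass` only
#' scales the reported per-segment masses (attribute `"segment_masses_kg"`),
#' never the CM position.
#'
#' @param traj a [trajectory3d()].
#' @param table anthropometric table, default [default_anthropometric_table()].
#' @param body_mass subject body mass (kg), optional.
#' @return object of class `cm_trajectory`: list with `fs`, `cm`
#'   (frames x 3, m), `v_res` (resultant CM speed, m/s) and `frame_index`.
#' @export
whole_body_cm <- function(traj, table = default_anthropometric_table(),
                          body_mass = NULL) {
  stopifnot(inherits(traj, "trajectory3d"))
  table <- validate_anthropometric_table(table)
  pos <- traj$positions
  used <- sort(unique(c(table$proximal_id, table$distal_id))) + 1L
  if (anyNA(pos[, used, ])) {
    bad <- which(apply(is.na(pos[, used, , drop = FALSE]), c(1, 2), any),
                 arr.ind = TRUE)[1L, ]
    stop_divekin(sprintf("missing landmark %d at frame %d",
                         used[bad[2L]] - 1L, traj$frame_index[bad[1L]]),
                 "divekin_missing_landmark")
  }
  w <- cm_landmark_weights(table)
  cm <- vapply(1:3, function(ax) pos[, , ax] %*% w, numeric(dim(pos)[1L]))
  cm <- matrix(cm, ncol = 3L, dimnames = list(NULL, c("X", "Y", "Z")))
  v_res <- if (nrow(cm) >= 3L) cm_velocity(cm, traj$fs)
           else rep(NA_real_, nrow(cm))      # too short to differentiate
  out <- structure(list(fs = traj$fs, cm = cm, v_res = v_res,
                        frame_index = traj$frame_index),
                   class = "cm_trajectory")
  if (!is.null(body_mass))
    attr(out, "segment_masses_kg") <-
      stats::setNames(table$mass_fraction * body_mass, table$segment)
  out
}

#' Resultant centre-of-mass speed
#'
#' Velocity by central finite differences on interior frames and one-sided
#' differences at the ends; the resultant is the Euclidean norm of the 3D
#' velocity vector.
#'
#' @param cm frames x 3 matrix of CM positions (m), or a `cm_trajectory`.
#' @param fs sampling rate (Hz).
#' @return numeric vector of resultant speeds (m/s), one per frame.
#' @export
cm_velocity <- function(cm, fs) {
  if (inherits(cm, "cm_trajectory")) { fs <- cm$fs; cm <- cm$cm }
  cm <- as.matrix(cm)
  n <- nrow(cm)
  if (n < 3L) stop("velocity needs >= 3 frames")
  vel <- matrix(0, n, 3L)
  vel[1L, ] <- (cm[2L, ] - cm[1L, ]) * fs
  vel[n, ] <- (cm[n, ] - cm[n - 1L, ]) * fs
  vel[2:(n - 1L), ] <- (cm[3:n, ] - cm[1:(n - 2L), ]) * fs / 2
  sqrt(rowSums(vel^2))
}

#' Knee joint angle
#'
#' Interior 3D angle at the knee between the knee-to-hip and knee-to-ankle
#' vectors, in degrees: 180 means full extension. The flexion convention
#' (`180 - interior`) is available via `convention = "flexion"`.
#'
#' @param traj a [trajectory3d()].
#' @param side `"left"` or `"right"` (hip 12/9, knee 13/10, ankle 14/11).
#' @param convention `"interior"` (default) or `"flexion"`.
#' @return numeric vector of angles (deg), one per frame.
#' @export
knee_angle <- function(traj, side, convention = c("interior", "flexion")) {
  stopifnot(inherits(traj, "trajectory3d"))
  convention <- match.arg(convention)
  ids <- side_landmarks(side)
  pos <- traj$positions
  u1 <- pos[, lm_col(ids$hip), , drop = FALSE] - pos[, lm_col(ids$knee), , drop = FALSE]
  u2 <- pos[, lm_col(ids$ankle), , drop = FALSE] - pos[, lm_col(ids$knee), , drop = FALSE]
  dim(u1) <- dim(u2) <- c(dim(pos)[1L], 3L)
  n1 <- sqrt(rowSums(u1^2)); n2 <- sqrt(rowSums(u2^2))
  if (any(n1 < 1e-12 | n2 < 1e-12)) {
    f <- which(n1 < 1e-12 | n2 < 1e-12)[1L]
    stop_divekin(sprintf("zero-length %s thigh/shank vector at frame %d: knee angle undefined",
                         side, traj$frame_index[f]), "divekin_undefined_angle")
  }
  cosang <- pmin(1, pmax(-1, rowSums(u1 * u2) / (n1 * n2)))
  ang <- acos(cosang) * 180 / pi
  if (convention == "flexion") 180 - ang else ang
}
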