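#' Construct a 2D pose sequence
#'
#' A `pose_sequence` holds one camera's time series of the 25 BODY_25
#' keypoints: image coordinates in pixels plus a per-keypoint detection
#' confidence. A keypoint with confidence 0 is missing and its coordinates
#' carry no information; a confidence of -1 marks a value repaired by
#' [fill_gaps()].
#'
#' @param camera_id camera label.
#' @param fs sampling rate in Hz (the study cameras ran at 120 Hz).
#' @param u,v numeric matrices, frames x 25, image coordinates in pixels.
#' @param conf numeric matrix, frames x 25, detection confidences.
#' @param frame_index integer vector of 0-based frame indices; must be
#'   contiguous and strictly increasing.
#' @return an object of class `pose_sequence`.
#' @export
pose_sequence <- function(camera_id, fs, u, v, conf,
                          frame_index = seq_len(nrow(u)) - 1L) {
  u <- as.matrix(u); v <- as.matrix(v); conf <- as.matrix(conf)
  n <- nrow(u)
  if (n == 0L) stop_divekin("pose sequence has zero frames", "divekin_empty_input")
  if (!all(dim(u) == c(n, N_KEYPOINTS)) || !all(dim(v) == c(n, N_KEYPOINTS)) ||
      !all(dim(conf) == c(n, N_KEYPOINTS)))
    stop("u, v and conf must each be frames x 25 matrices")
  if (!(is.numeric(fs) && length(fs) == 1L && fs > 0))
    stop("fs must be a positive scalar (Hz)")
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != n || any(diff(frame_index) != 1L))
    stop("frame_index must be contiguous and strictly increasing")
  structure(list(camera_id = as.character(camera_id), fs = fs,
                 u = u, v = v, conf = conf, frame_index = frame_index),
            class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> camera '%s': %d frames @ %g Hz, %.1f%% keypoints missing\n",
              x$camera_id, nrow(x$u), x$fs, 100 * mean(x$conf == 0)))
  invisible(x)
}

n_frames <- function(seq) nrow(seq$u)

#' Read a per-camera keypoint sequence
#'
#' Reads either a directory of OpenPose-style JSON files (one per frame,
#' each holding `people[[i]]$pose_keypoints_2d` as a flat 75-float vector)
#' or a single consolidated CSV with columns
#' `frame, keypoint_id, u, v, confidence`. When a frame contains several
#' detected people the one with the highest mean confidence is kept and a
#' message records the choice. A frame with no detected person becomes a
#' frame of 25 zero-confidence keypoints.
#'
#' @param path directory of per-frame JSON files, or a CSV file.
#' @param camera_id label attached to the returned sequence.
#' @param fs sampling rate in Hz.
#' @return a [pose_sequence()].
#' @export
read_pose_sequence <- function(path, camera_id, fs = 120) {
  if (!file.exists(path)) stop(sprintf("path does not exist: %s", path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    if (length(files) == 0L)
      stop_divekin(sprintf("no keypoint files found in %s", path), "divekin_empty_input")
    n <- length(files)
    u <- matrix(0, n, N_KEYPOINTS); v <- matrix(0, n, N_KEYPOINTS)
    conf <- matrix(0, n, N_KEYPOINTS)
    for (i in seq_len(n)) {
      rec <- tryCatch(jsonlite::fromJSON(files[i], simplifyVector = FALSE),
                      error = function(e)
                        stop(sprintf("malformed keypoint record in frame file '%s': %s",
                                     basename(files[i]), conditionMessage(e)),
                             call. = FALSE))
      people <- rec$people
      if (length(people) == 0L) next  # missing-person frame: all confidences 0
      kps <- lapply(people, function(p) {
        x <- unlist(p$pose_keypoints_2d)
        if (length(x) != 3L * N_KEYPOINTS)
          stop(sprintf("malformed keypoint record in frame file '%s': expected %d values, got %d",
                       basename(files[i]), 3L * N_KEYPOINTS, length(x)), call. = FALSE)
        matrix(x, ncol = 3L, byrow = TRUE)
      })
      pick <- 1L
      if (length(kps) > 1L) {
        pick <- which.max(vapply(kps, function(m) mean(m[, 3L]), 0))
        message(sprintf("frame %d (%s): %d people detected, kept person %d (highest mean confidence)",
                        i - 1L, basename(files[i]), length(kps), pick))
      }
      u[i, ] <- kps[[pick]][, 1L]
      v[i, ] <- kps[[pick]][, 2L]
      conf[i, ] <- kps[[pick]][, 3L]
    }
    pose_sequence(camera_id, fs, u, v, conf)
  } else {
    tab <- utils::read.csv(path)
    need <- c("frame", "keypoint_id", "u", "v", "confidence")
    if (!all(need %in% names(tab)))
      stop(sprintf("consolidated keypoint CSV must have columns %s",
                   paste(need, collapse = ", ")))
    frames <- sort(unique(tab$frame))
    if (length(frames) == 0L)
      stop_divekin("keypoint CSV holds zero frames", "divekin_empty_input")
    n <- length(frames)
    u <- matrix(0, n, N_KEYPOINTS); v <- matrix(0, n, N_KEYPOINTS)
    conf <- matrix(0, n, N_KEYPOINTS)
    ri <- match(tab$frame, frames)
    ci <- as.integer(tab$keypoint_id) + 1L
    if (any(ci < 1L | ci > N_KEYPOINTS))
      stop("keypoint_id out of range 0-24 in CSV")
    u[cbind(ri, ci)] <- tab$u
    v[cbind(ri, ci)] <- tab$v
    conf[cbind(ri, ci)] <- tab$confidence
    pose_sequence(camera_id, fs, u, v, conf, frame_index = frames)
  }
}

#' Write a pose sequence as per-frame OpenPose-style JSON files
#'
#' Inverse of the directory form of [read_pose_sequence()]; used both to
#' persist rendered synthetic views and to round-trip real streams.
#'
#' @param seq a [pose_sequence()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_pose_sequence <- function(seq, dir) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- n_frames(seq)
  paths <- character(n)
  for (i in seq_len(n)) {
    flat <- as.vector(rbind(seq$u[i, ], seq$v[i, ], seq$conf[i, ]))
    rec <- list(version = 1.3,
                people = list(list(pose_keypoints_2d = flat)))
    paths[i] <- file.path(dir, sprintf("%s_%012d_keypoints.json",
                                       seq$camera_id, seq$frame_index[i]))
    jsonlite::write_json(rec, paths[i], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Write a pose sequence as a consolidated long-format CSV
#'
#' @param seq a [pose_sequence()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_pose_csv <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  n <- n_frames(seq)
  tab <- data.frame(
    frame = rep(seq$frame_index, each = N_KEYPOINTS),
    keypoint_id = rep(0:(N_KEYPOINTS - 1L), n),
    u = as.vector(t(seq$u)), v = as.vector(t(seq$v)),
    confidence = as.vector(t(seq$conf)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Fill low-confidence gaps in a pose sequence
#'
#' Keypoint samples with confidence below `conf_min` are replaced by
#' piecewise-linear interpolation between the nearest flanking valid
#' frames; gaps at the ends of the sequence are held at the nearest valid
#' value. Repaired samples get confidence flag -1 and are listed in the
#' `"repairs"` attribute of the result (frame, keypoint_id). Any keypoint
#' with a gap longer than `max_gap` frames aborts with a
#' `divekin_gap_error`, mirroring the discarding of unusable trials.
#'
#' @param seq a [pose_sequence()].
#' @param conf_min confidence threshold in (0, 1]; samples below it are
#'   treated as missing. Default 0.1.
#' @param max_gap longest repairable gap, in frames. Default 12
#'   (0.1 s at 120 Hz).
#' @return a repaired [pose_sequence()] with a `"repairs"` attribute.
#' @export
fill_gaps <- function(seq, conf_min = 0.1, max_gap = 12L) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (!(conf_min > 0 && conf_min <= 1)) stop("conf_min must lie in (0, 1]")
  if (max_gap < 1L) stop("max_gap must be >= 1 frame")
  n <- n_frames(seq)
  u <- seq$u; v <- seq$v; conf <- seq$conf
  rep_frames <- integer(0); rep_kp <- integer(0)
  for (j in seq_len(N_KEYPOINTS)) {
    valid <- conf[, j] >= conf_min | conf[, j] == -1  # -1 = already repaired
    if (all(valid)) next
    if (!any(valid))
      stop_divekin(sprintf("keypoint %d has no valid frames", j - 1L),
                   "divekin_gap_error", keypoint = j - 1L, gap = n)
    r <- rle(!valid)
    if (max(r$lengths[r$values]) > max_gap)
      stop_divekin(
        sprintf("keypoint %d has a %d-frame gap exceeding max_gap = %d; trial unusable",
                j - 1L, max(r$lengths[r$values]), max_gap),
        "divekin_gap_error", keypoint = j - 1L,
        gap = max(r$lengths[r$values]))
    idx <- which(valid)
    bad <- which(!valid)
    u[bad, j] <- stats::approx(idx, u[idx, j], xout = bad, rule = 2)$y
    v[bad, j] <- stats::approx(idx, v[idx, j], xout = bad, rule = 2)$y
    conf[bad, j] <- -1
    rep_frames <- c(rep_frames, seq$frame_index[bad])
    rep_kp <- c(rep_kp, rep_len(j - 1L, length(bad)))
  }
  out <- pose_sequence(seq$camera_id, seq$fs, u, v, conf, seq$frame_index)
  attr(out, "repairs") <- data.frame(frame = rep_frames, keypoint_id = rep_kp)
  out
}
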