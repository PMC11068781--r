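#' Estimate the ground height from the standing phase
#'
#' The per-trial ground reference is the 5th percentile of the heel and
#' big-toe landmark heights over the pre-dive standing phase (by default
#' the first 10% of frames, at least 5).
#'
#' @param traj a [trajectory3d()].
#' @param stand_frames number of initial frames treated as quiet standing;
#'   default `max(5, floor(0.1 * n))`.
#' @return scalar ground height (m).
#' @export
estimate_ground_z <- function(traj, stand_frames = NULL) {
  stopifnot(inherits(traj, "trajectory3d"))
  n <- dim(traj$positions)[1L]
  if (is.null(stand_frames)) stand_frames <- max(5L, floor(0.1 * n))
  stand_frames <- min(stand_frames, n)
  foot_ids <- lm_col(c(BODY25$l_heel, BODY25$r_heel, BODY25$l_big_toe, BODY25$r_big_toe))
  as.numeric(stats::quantile(traj$positions[seq_len(stand_frames), foot_ids, 3L],
                             0.05, names = FALSE))
}

#' Detect the dive side from the CM path
#'
#' The side is the sign of the net mediolateral (Y) CM displacement over
#' the trial; in the field frame +Y points toward the goalkeeper's left.
#' A displacement below `threshold` is ambiguous and raises an error.
#'
#' @param cm a `cm_trajectory` (from [whole_body_cm()]) or frames x 3 matrix.
#' @param threshold minimum |net Y displacement| (m). Default 0.2.
#' @param positive_y which side +Y maps to; default `"left"`.
#' @return `"left"` or `"right"`.
#' @export
detect_dive_side <- function(cm, threshold = 0.2, positive_y = c("left", "right")) {
  positive_y <- match.arg(positive_y)
  if (inherits(cm, "cm_trajectory")) cm <- cm$cm
  if (nrow(cm) < 10L) stop("side detection needs >= 10 frames")
  dy <- cm[nrow(cm), 2L] - cm[1L, 2L]
  if (abs(dy) < threshold)
    stop_divekin(sprintf(
      "net mediolateral CM displacement %.3f m below %.2f m: dive side ambiguous",
      dy, threshold), "divekin_ambiguous_side")
  other <- if (positive_y == "left") "right" else "left"
  if (dy > 0) positive_y else other
}

#' Detect ipsilateral foot-off and ground-contact events
#'
#' The foot is "off" at a frame when both its heel and big-toe landmarks
#' sit above `ground_z + eps` for at least `k` consecutive frames. The
#' dive cycle starts at the first frame of the first off-period
#' (`t_start`); `t_land` is the first frame of the final contact period
#' (the step landing); `t_last_contact` is the last on-ground frame before
#' the final sustained off-period, whose first frame is `t_final_off`.
#' This captures the frontal-step pattern: step off, land, push off for
#' the final departure.
#'
#' @param traj a [trajectory3d()].
#' @param side `"left"` or `"right"`.
#' @param ground_z ground height (m); see [estimate_ground_z()].
#' @param eps height margin above ground counting as "off" (m). Default 0.03.
#' @param k minimum off-period length (frames). Default 3.
#' @return list with 0-based frames `t_first_contact` (first on-ground
#'   frame of the trial), `t_start`, `t_land`, `t_last_contact`,
#'   `t_final_off`.
#' @export
detect_foot_events <- function(traj, side, ground_z = estimate_ground_z(traj),
                               eps = 0.03, k = 3L) {
  stopifnot(inherits(traj, "trajectory3d"), eps > 0, k >= 1L)
  ids <- side_landmarks(side)
  heel_z <- traj$positions[, lm_col(ids$heel), 3L]
  toe_z <- traj$positions[, lm_col(ids$big_toe), 3L]
  off <- heel_z > ground_z + eps & toe_z > ground_z + eps
  r <- rle(off)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= k
  if (!any(keep))
    stop_divekin(sprintf("%s foot never leaves the ground for >= %d frames: no dive detected",
                         side, k), "divekin_no_dive")
  if (!any(!off))
    stop_divekin(sprintf("%s foot never touches the ground: bad trial", side),
                 "divekin_bad_trial")
  first_off <- starts[keep][1L]
  final_off <- starts[keep][sum(keep)]
  on_before <- which(!off[seq_len(final_off - 1L)])
  if (length(on_before) == 0L)
    stop_divekin(sprintf("%s foot has no ground contact before its final departure", side),
                 "divekin_bad_trial")
  last_on <- on_before[length(on_before)]
  # first frame of the contact period that ends at last_on
  contact_run_start <- last_on
  while (contact_run_start > 1L && !off[contact_run_start - 1L])
    contact_run_start <- contact_run_start - 1L
  fi <- traj$frame_index
  list(t_first_contact = fi[which(!off)[1L]],
       t_start = fi[first_off], t_land = fi[contact_run_start],
       t_last_contact = fi[last_on], t_final_off = fi[final_off])
}

#' Locate the peak resultant CM velocity
#'
#' PRV is the maximum of the resultant CM speed over the window from the
#' first ipsilateral foot-off to the last ipsilateral ground contact plus
#' `lookahead` frames (6 frames = 50 ms at 120 Hz, excluding the free-fall
#' portion of the dive). Ties break to the first frame attaining the
#' maximum.
#'
#' @param v_res resultant speed series (m/s).
#' @param t_start,t_last_contact 0-based event frames.
#' @param fs sampling rate (Hz); kept for interface symmetry and logging.
#' @param lookahead frames past `t_last_contact` included in the search
#'   window. Default 6.
#' @return list with `prv` (m/s) and `t_prv` (0-based frame).
#' @export
find_prv <- function(v_res, t_start, t_last_contact, fs = 120, lookahead = 6L) {
  n <- length(v_res)
  hi <- t_last_contact + lookahead
  if (hi > n - 1L) {
    warning(sprintf("PRV window end %d clamped to series end %d", hi, n - 1L))
    hi <- n - 1L
  }
  if (t_start > hi) stop("empty PRV search window")
  win <- (t_start:hi) + 1L
  i <- which.max(v_res[win])
  list(prv = v_res[win][i], t_prv = t_start + i - 1L)
}

#' Normalize a series onto the 0-100% dive cycle
#'
#' Linearly interpolates the series between `t_start` and `t_prv` onto
#' `n_nodes` equally spaced points; node 1 holds the `t_start` value and
#' the last node the `t_prv` value.
#'
#' @param series numeric series sampled at the trajectory frame rate.
#' @param t_start,t_prv 0-based event frames with `t_prv > t_start`.
#' @param n_nodes number of grid nodes. Default 101 (1% steps).
#' @return numeric vector of length `n_nodes`.
#' @export
normalize_cycle <- function(series, t_start, t_prv, n_nodes = 101L) {
  if (t_prv <= t_start) stop("normalization window needs t_prv > t_start")
  if (t_prv + 1L > length(series)) stop("series does not cover the cycle window")
  frames <- t_start:t_prv
  stats::approx(frames, series[frames + 1L],
                xout = seq(t_start, t_prv, length.out = n_nodes))$y
}

#' Assemble a dive cycle description
#'
#' @param side dive side.
#' @param t_start,t_land,t_last_contact,t_final_off,t_prv 0-based event frames.
#' @param prv peak resultant velocity (m/s).
#' @param n_nodes normalized grid size. Default 101.
#' @param lookahead the PRV lookahead used (frames).
#' @return object of class `dive_cycle`.
#' @export
dive_cycle <- function(side, t_start, t_land, t_last_contact, t_final_off,
                       t_prv, prv, n_nodes = 101L, lookahead = 6L) {
  if (!(t_start <= t_last_contact && t_last_contact < t_prv &&
        t_prv <= t_last_contact + lookahead))
    stop_divekin(sprintf(
      "dive-cycle ordering violated: t_start=%d, t_last_contact=%d, t_prv=%d (lookahead %d)",
      t_start, t_last_contact, t_prv, lookahead), "divekin_bad_cycle")
  structure(list(side = side, t_start = t_start, t_land = t_land,
                 t_last_contact = t_last_contact, t_final_off = t_final_off,
                 t_prv = t_prv, prv = prv,
                 grid = seq(0, 100, length.out = n_nodes)),
            class = "dive_cycle")
}

#' @export
print.dive_cycle <- function(x, ...) {
  cat(sprintf("<dive_cycle> side=%s  t_start=%d  t_land=%d  t_last_contact=%d  t_prv=%d  PRV=%.3f m/s\n",
              x$side, x$t_start, x$t_land, x$t_last_contact, x$t_prv, x$prv))
  invisible(x)
}
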