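#' Time to reach peak resultant velocity
#'
#' Absolute time between the first ipsilateral foot-off and the PRV frame.
#'
#' @param t_start,t_prv 0-based event frames with `t_prv > t_start`.
#' @param fs sampling rate (Hz).
#' @return time in seconds.
#' @export
compute_trprv <- function(t_start, t_prv, fs) {
  if (t_prv <= t_start) stop("TRPRV needs t_prv > t_start")
  (t_prv - t_start) / fs
}

#' Frontal step distance
#'
#' Anteroposterior (X) displacement of the ipsilateral big toe between the
#' first foot-off and the first frame of the final off-period, signed
#' positive toward the penalty mark.
#'
#' @param traj a [trajectory3d()].
#' @param side dive side.
#' @param t_start first ipsilateral foot-off (0-based frame).
#' @param t_final_off first frame of the final off-period
#'   (from [detect_foot_events()]).
#' @return signed distance (m).
#' @export
compute_fsd <- function(traj, side, t_start, t_final_off) {
  toe <- lm_col(side_landmarks(side)$big_toe)
  x <- traj$positions[c(t_start, t_final_off) + 1L, toe, 1L]
  if (anyNA(x))
    stop_divekin(sprintf("big-toe landmark missing at frame %d or %d", t_start, t_final_off),
                 "divekin_missing_landmark")
  x[2L] - x[1L]
}

#' Leg length from hip, knee and ground-extrapolated ankle
#'
#' `|hip - knee| + |knee - ankle'|`, where `ankle'` is the ankle landmark
#' with its vertical coordinate replaced by the heel's, so the measure
#' reaches the point closest to the ground.
#'
#' @param traj a [trajectory3d()].
#' @param side body side.
#' @param t_ref 0-based reference frame (typically quiet standing).
#' @return length (m).
#' @export
leg_length <- function(traj, side, t_ref) {
  ids <- side_landmarks(side)
  p <- traj$positions[t_ref + 1L, , ]
  hip <- p[lm_col(ids$hip), ]; knee <- p[lm_col(ids$knee), ]
  ankle <- p[lm_col(ids$ankle), ]; heel_z <- p[lm_col(ids$heel), 3L]
  if (anyNA(c(hip, knee, ankle, heel_z)))
    stop_divekin(sprintf("leg landmarks missing at frame %d", t_ref),
                 "divekin_missing_landmark")
  ankle[3L] <- heel_z
  sqrt(sum((hip - knee)^2)) + sqrt(sum((knee - ankle)^2))
}

#' Distance between the legs in the preparatory posture
#'
#' 3D heel-to-heel distance at the first frame of the ipsilateral foot's
#' last ground-contact period, divided by leg length. Stored as a ratio
#' (published group values sit around 0.73-0.80 of leg length); multiply
#' by 100 for the percentage form.
#'
#' @param traj a [trajectory3d()].
#' @param t_ref 0-based frame of the start of the last ipsilateral contact
#'   period (`t_land` from [detect_foot_events()]).
#' @param leg_len leg length (m), see [leg_length()].
#' @return unitless ratio.
#' @export
compute_dblpp <- function(traj, t_ref, leg_len) {
  if (!(leg_len > 0)) stop("leg length must be positive")
  p <- traj$positions[t_ref + 1L, , ]
  hl <- p[lm_col(BODY25$l_heel), ]; hr <- p[lm_col(BODY25$r_heel), ]
  if (anyNA(c(hl, hr)))
    stop_divekin(sprintf("heel landmark missing at frame %d", t_ref),
                 "divekin_missing_landmark")
  sqrt(sum((hl - hr)^2)) / leg_len
}

#' Frontal departure angle
#'
#' Horizontal-plane angle of the CM displacement between the first and the
#' last ipsilateral ground-contact frames, measured from the mediolateral
#' (Y) axis: 0 deg is a dive parallel to the goal line, 90 deg straight
#' toward the penalty mark. The instructional target is 18 deg.
#'
#' @param cm a `cm_trajectory` or frames x 3 matrix of CM positions.
#' @param t_first_contact,t_last_contact 0-based event frames.
#' @return angle in degrees, in [0, 90].
#' @export
compute_fda <- function(cm, t_first_contact, t_last_contact) {
  if (inherits(cm, "cm_trajectory")) cm <- cm$cm
  d <- cm[t_last_contact + 1L, ] - cm[t_first_contact + 1L, ]
  dx <- abs(d[1L]); dy <- abs(d[2L])
  if (dx < 1e-9 && dy < 1e-9)
    stop_divekin("horizontal CM displacement is zero: departure angle undefined",
                 "divekin_undefined_angle")
  unname(atan2(dx, dy) * 180 / pi)
}

#' Bundle the six per-trial dive variables
#'
#' @param prv peak resultant velocity (m/s).
#' @param trprv time to PRV (s).
#' @param fsd frontal step distance (m).
#' @param dblpp stance width as a ratio of leg length.
#' @param fda frontal departure angle (deg).
#' @param knee_curve 101-node normalized knee-angle curve (deg).
#' @param speed_curve 101-node normalized resultant CM speed curve (m/s).
#' @return object of class `dive_variables`.
#' @export
dive_variables <- function(prv, trprv, fsd, dblpp, fda,
                           knee_curve = NULL, speed_curve = NULL) {
  stopifnot(prv > 0, trprv > 0, dblpp >= 0, fda >= 0, fda <= 90)
  structure(list(prv = prv, trprv = trprv, fsd = fsd, dblpp = dblpp,
                 fda = fda, knee_curve = knee_curve, speed_curve = speed_curve),
            class = "dive_variables")
}

#' @export
print.dive_variables <- function(x, ...) {
  cat(sprintf(paste0("<dive_variables> PRV=%.3f m/s  TRPRV=%.3f s  FSD=%.3f m  ",
                     "DBLPP=%.3f (%.1f%% leg)  FDA=%.2f deg\n"),
              x$prv, x$trprv, x$fsd, x$dblpp, 100 * x$dblpp, x$fda))
  invisible(x)
}

#' @export
as.data.frame.dive_variables <- function(x, ...) {
  data.frame(prv = x$prv, trprv = x$trprv, fsd = x$fsd,
             dblpp = x$dblpp, fda = x$fda)
}
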