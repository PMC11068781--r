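#' Specify a synthetic penalty dive
#'
#' Parameters of the ground-truth dive motion produced by
#' [generate_dive_3d()]. The defaults encode the instructional targets for
#' a well-executed dive: preparatory stance at 75% of leg length, a
#' frontal step, an 18 degree frontal departure angle, and a maximal
#' impulse reaching peak speed quickly.
#'
#' @param side dive side, `"left"` or `"right"`.
#' @param fs sampling rate (Hz). Default 120.
#' @param duration trial length (s). Default 2.
#' @param stance_ratio target stance width at the step landing, as a
#'   fraction of leg length (the DBLPP target). Default 0.75.
#' @param step_length anteroposterior length of the frontal step (m, the
#'   FSD target). Default 0.45.
#' @param departure_angle horizontal CM departure angle from the goal line
#'   (deg, the FDA target). Default 18.
#' @param knee_min_angle deepest interior knee angle of the ipsilateral
#'   leg during the impulse (deg); realized approximately by adapting the
#'   squat depth. Default 110.
#' @param flexion_timing fraction of the impulse at which the squat
#'   reaches full depth. Default 0.6.
#' @param peak_speed peak resultant CM speed (m/s, the PRV target).
#'   Default 3.
#' @param impulse_duration time from first ipsilateral foot-off to peak
#'   speed (s, the TRPRV target). Default 0.55.
#' @param leg_length subject leg length (m). Default 0.88.
#' @param body_mass subject mass (kg); metadata only. Default 80.
#' @param elevation_angle constant elevation of the CM velocity above the
#'   horizontal during the impulse (deg). Default 8.
#' @param stand_time quiet-standing phase before the first foot-off (s).
#'   Default 0.4.
#' @param step_fraction fraction of the impulse spent with the stepping
#'   foot airborne. Default 0.45.
#' @param contra_off_fraction fraction of the impulse at which the
#'   contralateral foot leaves the ground. Default 0.55.
#' @param noise_px image-noise SD (px) used by [render_views()]. Default 0.
#' @param dropout_rate per-keypoint missing probability used by
#'   [render_views()]. Default 0.
#' @param seed RNG seed used by [render_views()]. Default 1.
#' @return object of class `synthetic_dive_spec`.
#' @export
synthetic_dive_spec <- function(side = "left", fs = 120, duration = 2,
                                stance_ratio = 0.75, step_length = 0.45,
                                departure_angle = 18, knee_min_angle = 110,
                                flexion_timing = 0.6, peak_speed = 3,
                                impulse_duration = 0.55, leg_length = 0.88,
                                body_mass = 80, elevation_angle = 8,
                                stand_time = 0.4, step_fraction = 0.45,
                                contra_off_fraction = 0.55,
                                noise_px = 0, dropout_rate = 0, seed = 1L) {
  side <- match.arg(side, c("left", "right"))
  spec <- list(side = side, fs = fs, duration = duration,
               stance_ratio = stance_ratio, step_length = step_length,
               departure_angle = departure_angle,
               knee_min_angle = knee_min_angle,
               flexion_timing = flexion_timing, peak_speed = peak_speed,
               impulse_duration = impulse_duration, leg_length = leg_length,
               body_mass = body_mass, elevation_angle = elevation_angle,
               stand_time = stand_time, step_fraction = step_fraction,
               contra_off_fraction = contra_off_fraction,
               noise_px = noise_px, dropout_rate = dropout_rate,
               seed = as.integer(seed))
  pos <- c("fs", "duration", "stance_ratio", "step_length", "peak_speed",
           "impulse_duration", "leg_length", "body_mass", "stand_time")
  for (p in pos) if (!(spec[[p]] > 0))
    stop(sprintf("spec field '%s' must be positive", p))
  if (departure_angle < 0 || departure_angle > 90)
    stop("departure_angle must lie in [0, 90] degrees")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (noise_px < 0) stop("noise_px must be >= 0")
  if (stand_time + impulse_duration >= duration)
    stop("physically inconsistent spec: stand_time + impulse_duration must be < duration")
  if (stance_ratio * leg_length <= step_length)
    stop(paste("physically inconsistent spec: the stance target",
               "(stance_ratio * leg_length) must exceed step_length"))
  if (knee_min_angle <= 60 || knee_min_angle >= 170)
    stop("knee_min_angle must lie in (60, 170) degrees")
  structure(spec, class = "synthetic_dive_spec")
}

## upper-body landmark offsets (m) relative to the pelvis origin (mid-hip),
## for a subject with 0.88 m legs; scaled linearly with leg length
upper_body_offsets <- function(scale = 1) {
  off <- rbind(
    nose       = c(0.08,  0.000, 0.62),
    neck       = c(0.00,  0.000, 0.50),
    r_shoulder = c(0.00, -0.200, 0.47),
    r_elbow    = c(0.03, -0.260, 0.21),
    r_wrist    = c(0.05, -0.280, -0.03),
    l_shoulder = c(0.00,  0.200, 0.47),
    l_elbow    = c(0.03,  0.260, 0.21),
    l_wrist    = c(0.05,  0.280, -0.03),
    mid_hip    = c(0.00,  0.000, 0.00),
    r_hip      = c(0.00, -0.100, 0.00),
    l_hip      = c(0.00,  0.100, 0.00),
    r_eye      = c(0.10, -0.035, 0.66),
    l_eye      = c(0.10,  0.035, 0.66),
    r_ear      = c(0.03, -0.080, 0.64),
    l_ear      = c(0.03,  0.080, 0.64))
  off * scale
}

## two-link inverse kinematics: knee position given hip H and ankle A
## (n x 3 each), thigh length a, shank length b, bending toward +X.
## Overstretched frames place the knee on the hip-ankle line.
knee_ik <- function(H, A, a, b) {
  d <- A - H
  D <- sqrt(rowSums(d^2))
  D <- pmin(D, (a + b) * 0.9999)
  nhat <- d / D
  x_d <- (a^2 - b^2 + D^2) / (2 * D)
  h <- sqrt(pmax(a^2 - x_d^2, 0))
  # forward bend axis: +X orthogonalized against the hip-ankle direction
  wx <- 1 - nhat[, 1L] * nhat[, 1L]
  wy <- -nhat[, 1L] * nhat[, 2L]
  wz <- -nhat[, 1L] * nhat[, 3L]
  wn <- sqrt(wx^2 + wy^2 + wz^2)
  wn[wn < 1e-9] <- 1
  H + x_d * nhat + h * cbind(wx, wy, wz) / wn
}

## mirror a trajectory about the X-Z plane: Y -> -Y plus left/right
## landmark relabeling (anatomical sides swap under reflection)
mirror_trajectory <- function(pos) {
  swap <- seq_len(N_KEYPOINTS)
  pairs <- rbind(c(2, 5), c(3, 6), c(4, 7), c(9, 12), c(10, 13), c(11, 14),
                 c(15, 16), c(17, 18), c(19, 22), c(20, 23), c(21, 24))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L] + 1L; j <- pairs[r, 2L] + 1L
    swap[c(i, j)] <- swap[c(j, i)]
  }
  out <- pos[, swap, , drop = FALSE]
  out[, , 2L] <- -out[, , 2L]
  out
}

#' Generate a ground-truth 3D dive motion
#'
#' Builds a kinematically plausible 25-landmark dive: a quiet standing
#' phase; a frontal step by the ipsilateral foot; a whole-body CM that
#' follows an analytic path whose resultant speed rises as a half-cosine
#' ramp to `peak_speed` over `impulse_duration` along the departure
#' azimuth (with a squat and a fixed velocity elevation); legs posed by
#' two-link inverse kinematics, with the squat depth adapted so the
#' deepest ipsilateral knee angle approximates `knee_min_angle`. The
#' pelvis translation is solved per frame by fixed-point iteration so that
#' the segmental whole-body CM of the generated landmarks reproduces the
#' target CM path to numerical precision.
#'
#' The returned ground truth is recomputed from the generated noiseless
#' trajectory by the package's own definitions (events from the
#' height-threshold rule, variables from the landmark geometry), so it is
#' self-consistent by construction.
#'
#' @param spec a [synthetic_dive_spec()].
#' @return list with `trajectory` (a [trajectory3d()]) and `ground_truth`
#'   (list: `events`, `variables` (a [dive_variables()]), `cycle`,
#'   `ground_z`, `cm`, and the generating `spec`).
#' @export
generate_dive_3d <- function(spec = synthetic_dive_spec()) {
  stopifnot(inherits(spec, "synthetic_dive_spec"))
  sc <- spec$leg_length / 0.88
  l_thigh <- spec$leg_length / 2
  l_shank <- spec$leg_length / 2 - 0.06 * sc
  ankle_h <- 0.06 * sc          # ankle landmark height above the heel
  z_plant <- 0.02               # heel/toe landmark height when planted
  toe_dx <- 0.20 * sc
  target_dist <- spec$stance_ratio * spec$leg_length
  # lateral drift of the stepping foot so the landing stance hits the
  # DBLPP target while the initial stance stays plausible
  w0 <- min(0.42 * sc, sqrt(target_dist^2 - spec$step_length^2))
  y_step <- sqrt(target_dist^2 - spec$step_length^2) - w0

  n <- round(spec$duration * spec$fs)
  fs <- spec$fs
  t_start <- round(spec$stand_time * fs)            # 0-based first off frame
  n_imp <- round(spec$impulse_duration * fs)
  t_prv <- t_start + n_imp
  t_lc <- t_prv - 3L                                 # design last contact
  t_land <- t_start + round(spec$step_fraction * n_imp)
  t_con <- t_start + round(spec$contra_off_fraction * n_imp)
  if (t_land >= t_lc - 3L || t_con >= t_lc)
    stop("physically inconsistent spec: step or contralateral push-off ends after last contact")

  fda <- spec$departure_angle * pi / 180
  elev <- spec$elevation_angle * pi / 180
  dir_h <- c(sin(fda), cos(fda), 0)                  # canonical left dive

  tt <- (0:(n - 1L)) / fs
  ts <- t_start / fs; tp <- t_prv / fs
  Timp <- n_imp / fs; Tdec <- 0.12; alpha <- 0.75
  # resultant speed profile s(t): a truncated raised-cosine ramp, so the
  # speed still rises with nonzero slope into the peak (the push-off ends
  # at the peak), then a brisk decay once the impulse is over
  s <- numeric(n)
  ramp <- tt >= ts & tt <= tp
  s[ramp] <- spec$peak_speed * (1 - cos(pi * alpha * (tt[ramp] - ts) / Timp)) /
    (1 - cos(pi * alpha))
  dec <- tt > tp & tt <= tp + Tdec
  s[dec] <- spec$peak_speed * cos(pi * (tt[dec] - tp) / (2 * Tdec))

  build <- function(squat_depth) {
    # squat profile: smooth descent reaching full depth at flexion_timing
    squat <- -squat_depth * smoothstep01((tt - ts) / (spec$flexion_timing * Timp))
    vel <- outer(s, cos(elev) * dir_h) ; vel[, 3L] <- s * sin(elev)
    # trapezoid-integrated CM displacement plus the squat offset
    disp <- apply(vel, 2L, function(vc) cumsum((vc + c(0, vc[-n])) / 2) / fs)
    disp[, 3L] <- disp[, 3L] + squat

    # ---- feet (canonical left dive: left foot steps) ----
    heel_l0 <- c(0,  w0 / 2, z_plant)
    heel_r0 <- c(0, -w0 / 2, z_plant)
    foot <- function(heel0, events) {
      # events: list(step = c(t0, t1, dx, dy) or NULL, off = frame)
      hx <- rep(heel0[1L], n); hy <- rep(heel0[2L], n); hz <- rep(heel0[3L], n)
      if (!is.null(events$step)) {
        t0 <- events$step[1L]; t1 <- events$step[2L]
        nf <- t1 - t0                                # off frames t0 .. t1-1
        i <- (t0:(t1 - 1L)) + 1L
        tau <- (seq_len(nf)) / (nf + 1)
        hx[i] <- heel0[1L] + events$step[3L] * smoothstep01(tau * (nf + 1) / nf)
        hy[i] <- heel0[2L] + events$step[4L] * smoothstep01(tau * (nf + 1) / nf)
        hz[i] <- heel0[3L] + 0.15 * sc * pmin(1, sin(pi * tau) / sin(0.10 * pi))
        hx[(t1 + 1L):n] <- heel0[1L] + events$step[3L]
        hy[(t1 + 1L):n] <- heel0[2L] + events$step[4L]
      }
      off <- events$off                               # first frame of departure
      if (off <= n - 1L) {
        i <- (off:(n - 1L)) + 1L
        dtf <- ((off:(n - 1L)) - (off - 1L)) / fs      # 1/fs at first off frame
        plant_x <- hx[off]; plant_y <- hy[off]; plant_z <- hz[off]
        follow <- smoothstep01(dtf / 0.15)
        hx[i] <- plant_x + (disp[i, 1L] - disp[off, 1L]) * follow
        hy[i] <- plant_y + (disp[i, 2L] - disp[off, 2L]) * follow
        hz[i] <- plant_z + 0.05 * pmin(1, fs * dtf) + 0.35 * sc * smoothstep01(dtf / 0.35)
      }
      list(x = hx, y = hy, z = hz)
    }
    fl <- foot(heel_l0, list(step = c(t_start, t_land, spec$step_length, y_step),
                             off = t_lc + 1L))
    fr <- foot(heel_r0, list(step = NULL, off = t_con))

    pos <- array(NA_real_, c(n, N_KEYPOINTS, 3L))
    put <- function(id, x, y, z) {
      pos[, lm_col(id), 1L] <<- x; pos[, lm_col(id), 2L] <<- y
      pos[, lm_col(id), 3L] <<- z
    }
    for (sd in list(list(f = fl, ids = side_landmarks("left"), sgn = 1),
                    list(f = fr, ids = side_landmarks("right"), sgn = -1))) {
      put(sd$ids$heel, sd$f$x, sd$f$y, sd$f$z)
      put(sd$ids$big_toe, sd$f$x + toe_dx, sd$f$y, sd$f$z)
      put(sd$ids$small_toe, sd$f$x + 0.18 * sc, sd$f$y - sd$sgn * 0.04 * sc, sd$f$z)
      put(sd$ids$ankle, sd$f$x, sd$f$y, sd$f$z + ankle_h)
    }

    # ---- pelvis: fixed point so the whole-body CM tracks the target ----
    off_up <- upper_body_offsets(sc)
    d170 <- sqrt(l_thigh^2 + l_shank^2 - 2 * l_thigh * l_shank * cos(170 * pi / 180))
    dy0 <- abs(w0 / 2 - 0.10 * sc)
    pelvis_z0 <- z_plant + ankle_h + sqrt(d170^2 - dy0^2)
    u <- cbind(disp[, 1L], disp[, 2L], disp[, 3L] + pelvis_z0)
    tabw <- cm_landmark_weights(default_anthropometric_table())
    ankle_l <- cbind(fl$x, fl$y, fl$z + ankle_h)
    ankle_r <- cbind(fr$x, fr$y, fr$z + ankle_h)
    assemble <- function(u) {
      for (nm in rownames(off_up)) {
        id <- BODY25[[nm]]
        pos[, lm_col(id), 1L] <<- u[, 1L] + off_up[nm, 1L]
        pos[, lm_col(id), 2L] <<- u[, 2L] + off_up[nm, 2L]
        pos[, lm_col(id), 3L] <<- u[, 3L] + off_up[nm, 3L]
      }
      hip_l <- u + matrix(off_up["l_hip", ], n, 3L, byrow = TRUE)
      hip_r <- u + matrix(off_up["r_hip", ], n, 3L, byrow = TRUE)
      pos[, lm_col(BODY25$l_knee), ] <<- knee_ik(hip_l, ankle_l, l_thigh, l_shank)
      pos[, lm_col(BODY25$r_knee), ] <<- knee_ik(hip_r, ankle_r, l_thigh, l_shank)
      invisible(NULL)
    }
    assemble(u)
    cm_of <- function() vapply(1:3, function(ax) pos[, , ax] %*% tabw, numeric(n))
    cm0 <- cm_of()
    target <- cbind(cm0[1L, 1L] + disp[, 1L], cm0[1L, 2L] + disp[, 2L],
                    cm0[1L, 3L] + disp[, 3L])
    for (it in 1:14) {
      u <- u + (target - cm_of())
      assemble(u)
    }
    pos
  }

  # adapt squat depth toward the requested deepest ipsilateral knee angle
  chord <- function(th) sqrt(l_thigh^2 + l_shank^2 -
                               2 * l_thigh * l_shank * cos(th * pi / 180))
  depth <- 0.30 * sc
  pos <- build(depth)
  for (it in 1:6) {
    traj_tmp <- trajectory3d(pos, fs)
    # deepest ipsilateral knee flexion during the impulse stance
    # (landing to peak velocity); the brief dip during the step flight is
    # foot-lift kinematics, not the squat this parameter controls
    th_min <- min(knee_angle(traj_tmp, "left")[(t_land + 1L):(t_prv + 1L)])
    if (abs(th_min - spec$knee_min_angle) < 1) break
    depth <- max(0.05, depth + chord(min(th_min, 169)) - chord(spec$knee_min_angle))
    pos <- build(depth)
  }

  if (spec$side == "right") pos <- mirror_trajectory(pos)
  traj <- trajectory3d(pos, fs)

  # ground truth: the package's own definitions applied to the true motion
  cm <- whole_body_cm(traj, body_mass = spec$body_mass)
  gz <- estimate_ground_z(traj)
  ev <- detect_foot_events(traj, spec$side, gz)
  pk <- find_prv(cm$v_res, ev$t_start, ev$t_last_contact, fs)
  leg <- leg_length(traj, spec$side, 0L)
  vars <- dive_variables(
    prv = pk$prv,
    trprv = compute_trprv(ev$t_start, pk$t_prv, fs),
    fsd = compute_fsd(traj, spec$side, ev$t_start, ev$t_final_off),
    dblpp = compute_dblpp(traj, ev$t_land, leg),
    fda = compute_fda(cm, ev$t_first_contact, ev$t_last_contact),
    knee_curve = normalize_cycle(knee_angle(traj, spec$side), ev$t_start, pk$t_prv),
    speed_curve = normalize_cycle(cm$v_res, ev$t_start, pk$t_prv))
  cyc <- dive_cycle(spec$side, ev$t_start, ev$t_land, ev$t_last_contact,
                    ev$t_final_off, pk$t_prv, pk$prv)
  list(trajectory = traj,
       ground_truth = list(events = ev, cycle = cyc, variables = vars,
                           leg_length = leg, ground_z = gz, cm = cm,
                           spec = spec))
}
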