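#' Configuration for a single-trial analysis run
#'
#' Collects every processing constant of the pipeline under its
#' conventional default: gap repair thresholds, the 7 Hz 4th-order
#' zero-lag Butterworth filter (optionally auto-selected by residual
#' analysis), the foot-event height rule, the 6-frame PRV lookahead and
#' the 101-node normalization grid.
#'
#' @param conf_min,max_gap gap-repair settings, see [fill_gaps()].
#' @param filter_enabled smooth 2D coordinates before reconstruction.
#' @param filter_fc filter cutoff (Hz). Default 7.
#' @param auto_fc select the cutoff per trial by [residual_analysis_cutoff()]
#'   (applied to the first camera's mid-hip vertical coordinate).
#' @param fc_grid candidate grid for `auto_fc`.
#' @param eps,k foot-event height rule, see [detect_foot_events()].
#' @param ground_z fixed ground height (m); `NULL` estimates it per trial.
#' @param side dive side; `NULL` detects it from the CM path.
#' @param lookahead PRV lookahead (frames). Default 6.
#' @param n_nodes normalization grid size. Default 101.
#' @param trim_s filter-transient trim: this many seconds are dropped from
#'   each end of the smoothed streams before reconstruction (the first and
#'   last samples of a zero-lag filtered series carry inflated noise), and
#'   frames are renumbered from 0. Applied only when filtering is enabled.
#'   Default 0.15.
#' @param leg_ref_frame 0-based frame used to measure leg length
#'   (quiet standing). Default 0.
#' @param anthropometric_table segment table; `NULL` uses the default.
#' @param body_mass subject mass (kg), optional.
#' @return a list of class `trial_config`.
#' @export
trial_config <- function(conf_min = 0.1, max_gap = 12L, filter_enabled = TRUE,
                         filter_fc = 7, auto_fc = FALSE,
                         fc_grid = seq(1, 15, by = 0.5), eps = 0.03, k = 3L,
                         ground_z = NULL, side = NULL, lookahead = 6L,
                         n_nodes = 101L, trim_s = 0.15, leg_ref_frame = 0L,
                         anthropometric_table = NULL, body_mass = NULL) {
  structure(as.list(environment()), class = "trial_config")
}

#' Analyze one dive trial end to end
#'
#' Runs the full processing chain on one trial's per-camera keypoint
#' streams: gap repair, zero-lag smoothing of the 2D coordinates,
#' multi-view DLT reconstruction, whole-body CM, dive-side and foot-event
#' detection, PRV location, and the six outcome variables with the
#' normalized CM-speed and knee-angle curves. Trials failing the gap rule
#' or event detection are returned flagged `"discarded"` with a
#' machine-readable reason instead of raising, mirroring field practice of
#' discarding unusable trials. The run is deterministic: identical inputs
#' and configuration reproduce identical output.
#'
#' @param streams list of per-camera [pose_sequence()] (>= 2).
#' @param cameras list of matching [dlt_camera()].
#' @param config a [trial_config()].
#' @param trial_id label carried into results and messages.
#' @return object of class `dive_trial`: list with `status`
#'   (`"ok"`/`"discarded"`), `reason` (when discarded), `variables`,
#'   `cycle`, `trajectory`, `cm` and `qc` (repairs per camera, filter
#'   cutoff used, cameras used).
#' @export
run_trial <- function(streams, cameras, config = trial_config(),
                      trial_id = "trial") {
  stopifnot(length(streams) >= 2L, length(streams) == length(cameras))
  discard <- function(reason, cond) {
    structure(list(status = "discarded", trial_id = trial_id,
                   reason = reason, message = conditionMessage(cond)),
              class = "dive_trial")
  }
  res <- tryCatch({
    repaired <- lapply(streams, fill_gaps,
                       conf_min = config$conf_min, max_gap = config$max_gap)
    fc_used <- NA_real_
    if (config$filter_enabled) {
      fc_used <- config$filter_fc
      if (config$auto_fc) {
        fc_used <- as.numeric(residual_analysis_cutoff(
          repaired[[1L]]$v[, lm_col(BODY25$mid_hip)], repaired[[1L]]$fs,
          fc_grid = config$fc_grid, default_fc = config$filter_fc))
      }
      repaired <- lapply(repaired, smooth_pose_sequence, fc = fc_used)
    }
    trim <- 0L
    if (config$filter_enabled && config$trim_s > 0) {
      fs0 <- repaired[[1L]]$fs
      trim <- round(config$trim_s * fs0)
      nall <- nrow(repaired[[1L]]$u)
      if (nall - 2L * trim >= 120L) {     # keep trims sane on short trials
        keep <- (trim + 1L):(nall - trim)
        repaired <- lapply(repaired, function(s)
          pose_sequence(s$camera_id, s$fs, s$u[keep, ], s$v[keep, ],
                        s$conf[keep, ]))
      } else trim <- 0L
    }
    n <- nrow(repaired[[1L]]$u)
    fs <- repaired[[1L]]$fs
    pos <- array(NA_real_, c(n, N_KEYPOINTS, 3L))
    for (j in seq_len(N_KEYPOINTS)) {
      pos[, j, ] <- reconstruct_points(
        cameras,
        lapply(repaired, function(s) s$u[, j]),
        lapply(repaired, function(s) s$v[, j]))
    }
    traj <- trajectory3d(pos, fs, repaired[[1L]]$frame_index)
    table <- if (is.null(config$anthropometric_table))
      default_anthropometric_table() else config$anthropometric_table
    cm <- whole_body_cm(traj, table, config$body_mass)
    side <- if (is.null(config$side)) detect_dive_side(cm) else config$side
    gz <- if (is.null(config$ground_z)) estimate_ground_z(traj) else config$ground_z
    ev <- detect_foot_events(traj, side, gz, eps = config$eps, k = config$k)
    pk <- find_prv(cm$v_res, ev$t_start, ev$t_last_contact, fs,
                   lookahead = config$lookahead)
    leg <- leg_length(traj, side, config$leg_ref_frame)
    vars <- dive_variables(
      prv = pk$prv,
      trprv = compute_trprv(ev$t_start, pk$t_prv, fs),
      fsd = compute_fsd(traj, side, ev$t_start, ev$t_final_off),
      dblpp = compute_dblpp(traj, ev$t_land, leg),
      fda = compute_fda(cm, ev$t_first_contact, ev$t_last_contact),
      knee_curve = normalize_cycle(knee_angle(traj, side), ev$t_start,
                                   pk$t_prv, config$n_nodes),
      speed_curve = normalize_cycle(cm$v_res, ev$t_start, pk$t_prv,
                                    config$n_nodes))
    cyc <- dive_cycle(side, ev$t_start, ev$t_land, ev$t_last_contact,
                      ev$t_final_off, pk$t_prv, pk$prv,
                      n_nodes = config$n_nodes, lookahead = config$lookahead)
    structure(list(
      status = "ok", trial_id = trial_id, variables = vars, cycle = cyc,
      trajectory = traj, cm = cm,
      qc = list(filter_fc = fc_used, trim_frames = trim,
                side = side, ground_z = gz,
                cameras = vapply(cameras, function(c) c$camera_id, ""),
                repairs = lapply(repaired, attr, "repairs"))),
      class = "dive_trial")
  },
  divekin_gap_error = function(e) discard("gap", e),
  divekin_no_dive = function(e) discard("no_dive", e),
  divekin_bad_trial = function(e) discard("bad_trial", e),
  divekin_ambiguous_side = function(e) discard("ambiguous_side", e),
  divekin_bad_cycle = function(e) discard("bad_cycle", e))
  res
}

#' @export
print.dive_trial <- function(x, ...) {
  if (x$status == "discarded") {
    cat(sprintf("<dive_trial> %s DISCARDED (%s): %s\n",
                x$trial_id, x$reason, x$message))
  } else {
    cat(sprintf("<dive_trial> %s ok, side=%s\n", x$trial_id, x$cycle$side))
    print(x$variables)
  }
  invisible(x)
}

#' Study-level statistics on a cohort of analyzed trials
#'
#' Reproduces the study's statistical battery on a trial table plus
#' normalized curves (from [run_trial()] results or [generate_cohort()]):
#' per-variable mixed two-way repeated-measures ANOVA (group x condition)
#' with Bonferroni cell contrasts on subject-level means; paired t tests
#' with Cohen's d for the laterality comparison (DLL vs NDLL); and
#' permutation SPM paired t on the normalized CM-speed and knee-angle
#' curves for the four group/condition comparisons and for laterality.
#' Trials are averaged per subject and condition before inference, so the
#' pairing unit is the goalkeeper. Between-group SPM comparisons pair
#' subjects by position within their group, which is a design stand-in
#' documented in the vignette (the paired SPM tool is what this package
#' ships).
#'
#' @param trials data.frame with columns subject, group (`CG`/`VG`),
#'   condition (`pre`/`post`), side (`DLL`/`NDLL`) and the outcome
#'   variables `prv, trprv, fsd, dblpp, fda`.
#' @param speed_curves,knee_curves trial x 101 matrices aligned with
#'   `trials` rows (optional; SPM section is skipped when absent).
#' @param alpha significance level. Default 0.05.
#' @param n_perm SPM permutation budget. Default 10000 (exhaustive
#'   enumeration is used automatically at these subject counts).
#' @param seed seed for SPM permutations.
#' @return object of class `study_report`: list with `anova` (one
#'   [mixed_anova()] per variable), `laterality` (one [paired_t()] per
#'   variable), `spm` (named list of [spm_paired_t()] results) and `n`
#'   bookkeeping.
#' @export
run_study <- function(trials, speed_curves = NULL, knee_curves = NULL,
                      alpha = 0.05, n_perm = 10000L, seed = 1L) {
  need <- c("subject", "group", "condition", "side",
            "prv", "trprv", "fsd", "dblpp", "fda")
  if (!all(need %in% names(trials)))
    stop(sprintf("trials table needs columns %s", paste(need, collapse = ", ")))
  cells <- expand.grid(group = c("CG", "VG"), condition = c("pre", "post"))
  have <- unique(trials[, c("group", "condition")])
  miss <- !apply(cells, 1L, function(r)
    any(have$group == r[["group"]] & have$condition == r[["condition"]]))
  if (any(miss))
    stop_divekin(sprintf("design imbalance: missing cells %s",
                         paste(sprintf("%s:%s", cells$group[miss],
                                       cells$condition[miss]), collapse = ", ")),
                 "divekin_unbalanced_design")
  vars <- c("prv", "trprv", "fsd", "dblpp", "fda")

  agg_cond <- stats::aggregate(trials[vars],
                               by = trials[c("subject", "group", "condition")],
                               FUN = mean)
  anovas <- lapply(vars, function(v)
    mixed_anova(agg_cond[[v]], agg_cond$group, agg_cond$condition,
                agg_cond$subject, alpha = alpha))
  names(anovas) <- vars

  agg_side <- stats::aggregate(trials[vars],
                               by = trials[c("subject", "side")], FUN = mean)
  agg_side <- agg_side[order(agg_side$subject), ]
  lat <- lapply(vars, function(v) {
    x <- agg_side[[v]][agg_side$side == "DLL"]
    y <- agg_side[[v]][agg_side$side == "NDLL"]
    paired_t(x, y, label = sprintf("%s: DLL x NDLL", v))
  })
  names(lat) <- vars

  spm <- list()
  if (!is.null(speed_curves) && !is.null(knee_curves)) {
    subj_curves <- function(curves, sel) {
      # per-subject mean curve over the selected trials, rows = subjects
      s <- trials$subject[sel]
      m <- rowsum(curves[sel, , drop = FALSE], s) / as.vector(table(s))
      m[sort(unique(s)), , drop = FALSE]
    }
    comparisons <- list(
      cg_pre_x_cg_post = list(quote(group == "CG" & condition == "pre"),
                              quote(group == "CG" & condition == "post"), TRUE),
      vg_pre_x_vg_post = list(quote(group == "VG" & condition == "pre"),
                              quote(group == "VG" & condition == "post"), TRUE),
      cg_pre_x_vg_pre = list(quote(group == "CG" & condition == "pre"),
                             quote(group == "VG" & condition == "pre"), FALSE),
      cg_post_x_vg_post = list(quote(group == "CG" & condition == "post"),
                               quote(group == "VG" & condition == "post"), FALSE),
      dll_x_ndll = list(quote(side == "DLL"), quote(side == "NDLL"), TRUE))
    ci <- 0L
    for (nm in names(comparisons)) {
      cmp <- comparisons[[nm]]
      sel_a <- eval(cmp[[1L]], trials)
      sel_b <- eval(cmp[[2L]], trials)
      for (curve in c("speed", "knee")) {
        curves <- if (curve == "speed") speed_curves else knee_curves
        a <- subj_curves(curves, sel_a)
        b <- subj_curves(curves, sel_b)
        if (!cmp[[3L]]) {         # between groups: pair by within-group position
          rownames(a) <- rownames(b) <- NULL
        }
        ci <- ci + 1L
        spm[[sprintf("%s_%s", nm, curve)]] <-
          spm_paired_t(a, b, alpha = alpha, n_perm = n_perm,
                       seed = seed + ci)
      }
    }
  }
  structure(list(anova = anovas, laterality = lat, spm = spm,
                 alpha = alpha,
                 n = list(trials = nrow(trials),
                          subjects = length(unique(trials$subject)))),
            class = "study_report")
}

#' List the significant findings of a study report
#'
#' Screens every comparison a [run_study()] report contains under explicit
#' multiplicity control. Scalar cell contrasts are Bonferroni-adjusted:
#' with `method = "per_variable"` within each variable's four-contrast
#' post-hoc family (the conventional repeated-measures post hoc), with
#' `method = "battery"` across every scalar contrast in the report (a
#' conservative whole-screen control appropriate when the report is used
#' as a discovery screen). SPM comparisons are already family-wise
#' controlled across the cycle within each comparison; their cluster
#' p values are additionally Bonferroni-adjusted across SPM comparisons
#' under `method = "battery"`.
#'
#' @param report a `study_report`.
#' @param method `"battery"` (default) or `"per_variable"`.
#' @param alpha significance level; defaults to the report's.
#' @return data.frame with columns `type` (`scalar`/`spm`), `comparison`,
#'   `detail`, `p_adjusted` — one row per significant finding (zero rows
#'   when nothing survives).
#' @export
significant_findings <- function(report, method = c("battery", "per_variable"),
                                 alpha = NULL) {
  method <- match.arg(method)
  if (is.null(alpha)) alpha <- report$alpha
  rows <- list()
  all_scalar <- do.call(rbind, lapply(names(report$anova), function(v) {
    ct <- report$anova[[v]]$contrasts
    ct$variable <- v
    ct
  }))
  k <- if (method == "battery") nrow(all_scalar) else 4L
  all_scalar$p_adj <- pmin(1, all_scalar$p * k)
  sig <- all_scalar[all_scalar$p_adj < alpha, , drop = FALSE]
  if (nrow(sig) > 0L)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "scalar", comparison = sig$comparison, detail = sig$variable,
      p_adjusted = sig$p_adj)
  if (length(report$spm)) {
    kspm <- if (method == "battery") length(report$spm) else 1L
    for (nm in names(report$spm)) {
      cl <- report$spm[[nm]]$clusters
      if (nrow(cl) == 0L) next
      p_adj <- pmin(1, cl$p_value * kspm)
      keep <- p_adj < alpha
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          type = "spm", comparison = nm,
          detail = sprintf("%.1f-%.1f%%", cl$start_pct[keep], cl$end_pct[keep]),
          p_adjusted = p_adj[keep])
    }
  }
  if (length(rows) == 0L)
    return(data.frame(type = character(0), comparison = character(0),
                      detail = character(0), p_adjusted = numeric(0)))
  do.call(rbind, rows)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d trials, %d goalkeepers (alpha = %g)\n",
              x$n$trials, x$n$subjects, x$alpha))
  for (v in names(x$anova)) {
    at <- x$anova[[v]]$anova_table
    cat(sprintf("  %s: group F(%d,%d)=%.2f p=%.3f | time F(%d,%d)=%.2f p=%.3f | interaction F(%d,%d)=%.2f p=%.3f\n",
                v, at$df1[1], at$df2[1], at$F[1], at$p[1],
                at$df1[2], at$df2[2], at$F[2], at$p[2],
                at$df1[3], at$df2[3], at$F[3], at$p[3]))
  }
  cat("laterality (DLL x NDLL, paired t):\n")
  for (v in names(x$laterality))
    cat(sprintf("  %s: t=%.2f p=%.3f d=%.2f\n", v,
                x$laterality[[v]]$statistic, x$laterality[[v]]$p_value,
                x$laterality[[v]]$effect_size_d))
  if (length(x$spm)) {
    sig <- vapply(x$spm, function(s) nrow(s$clusters) > 0L, TRUE)
    cat(sprintf("SPM: %d/%d comparisons with suprathreshold clusters: %s\n",
                sum(sig), length(sig),
                if (any(sig)) paste(names(x$spm)[sig], collapse = ", ") else "-"))
  }
  invisible(x)
}
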