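#' Generate a study-shaped cohort of dive outcomes
#'
#' Builds a dataset shaped like the field study: two groups (control
#' `"CG"` and video-instruction `"VG"`) of `n_per_group` goalkeepers, each
#' measured pre and post, diving to both the dominant (`"DLL"`) and
#' non-dominant (`"NDLL"`) side, with `n_trials` trials per subject x
#' condition x side cell. Scalar variables are drawn from a
#' subject-random-intercept model around realistic field values; the
#' normalized CM-speed and knee-angle curves are smooth template curves
#' with subject and trial variation. Optional effect shifts emulate an
#' instructional-video response in the VG post condition and a laterality
#' effect, so the statistical machinery can be exercised on study-shaped
#' input with known signal.
#'
#' @param n_per_group goalkeepers per group. Default 4.
#' @param n_trials trials per subject x condition x side cell. Default 4.
#' @param effects optional list of injected shifts:
#'   `vg_post` (named shifts added to VG post trials, e.g.
#'   `list(fsd = 0.15, trprv = -0.05, fda = 3, knee = list(shift = 8,
#'   window = c(55, 75)))`) and `ndll` (shifts added to NDLL trials, same
#'   form). Default: none (a null cohort).
#' @param seed RNG seed.
#' @return list with `trials` (data.frame: trial_id, subject, group,
#'   condition, side, prv, trprv, fsd, dblpp, fda), `speed_curves` and
#'   `knee_curves` (trial x 101 matrices, rows matching `trials`).
#' @export
generate_cohort <- function(n_per_group = 4L, n_trials = 4L,
                            effects = list(), seed = 1L) {
  set.seed(seed)
  base <- list(prv = 3.0, trprv = 0.54, fsd = 0.35, dblpp = 0.75, fda = 14)
  sd_subj <- list(prv = 0.25, trprv = 0.05, fsd = 0.12, dblpp = 0.10, fda = 4.5)
  sd_trial <- list(prv = 0.12, trprv = 0.035, fsd = 0.06, dblpp = 0.035, fda = 2.5)
  vars <- names(base)

  subjects <- sprintf("S%02d", seq_len(2L * n_per_group))
  groups <- rep(c("CG", "VG"), each = n_per_group)
  subj_eff <- lapply(vars, function(v) stats::rnorm(length(subjects), 0, sd_subj[[v]]))
  names(subj_eff) <- vars

  grid <- expand.grid(subject = seq_along(subjects),
                      condition = c("pre", "post"), side = c("DLL", "NDLL"),
                      trial = seq_len(n_trials), stringsAsFactors = FALSE)
  m <- nrow(grid)
  pct <- seq(0, 100, length.out = 101L)
  speed_curves <- matrix(0, m, 101L)
  knee_curves <- matrix(0, m, 101L)
  tab <- data.frame(trial_id = sprintf("T%04d", seq_len(m)),
                    subject = subjects[grid$subject],
                    group = groups[grid$subject],
                    condition = grid$condition, side = grid$side)
  shift_of <- function(eff, v) if (!is.null(eff[[v]]) && !is.list(eff[[v]])) eff[[v]] else 0

  for (v in vars) {
    val <- base[[v]] + subj_eff[[v]][grid$subject] +
      stats::rnorm(m, 0, sd_trial[[v]])
    is_vgpost <- tab$group == "VG" & tab$condition == "post"
    val[is_vgpost] <- val[is_vgpost] + shift_of(effects$vg_post, v)
    is_ndll <- tab$side == "NDLL"
    val[is_ndll] <- val[is_ndll] + shift_of(effects$ndll, v)
    tab[[v]] <- val
  }
  tab$prv <- pmax(tab$prv, 0.5)
  tab$trprv <- pmax(tab$trprv, 0.1)
  tab$dblpp <- pmax(tab$dblpp, 0.05)
  tab$fda <- pmin(pmax(tab$fda, 0), 90)

  knee_shift <- function(eff) {
    k <- eff$knee
    if (is.null(k)) return(numeric(101L))
    w <- pct >= k$window[1L] & pct <= k$window[2L]
    out <- numeric(101L)
    # smooth plateau over the window
    out[w] <- k$shift * sin(pi * (pct[w] - k$window[1L]) /
                              (k$window[2L] - k$window[1L]))
    out
  }
  sh_vgpost <- knee_shift(effects$vg_post)
  sh_ndll <- knee_shift(effects$ndll)

  for (r in seq_len(m)) {
    prv <- tab$prv[r]
    wig <- stats::rnorm(3L, 0, 1)
    speed_curves[r, ] <- prv * 0.5 * (1 - cos(pi * pct / 100)) +
      0.05 * prv * (wig[1L] * sin(pi * pct / 100) + wig[2L] * sin(2 * pi * pct / 100))
    knee <- 170 - 62 * sin(pi * pct / 100)^2 +
      4 * (wig[3L] * sin(pi * pct / 100)) + stats::rnorm(1L, 0, 2.5)
    if (tab$group[r] == "VG" && tab$condition[r] == "post") knee <- knee + sh_vgpost
    if (tab$side[r] == "NDLL") knee <- knee + sh_ndll
    knee_curves[r, ] <- knee
    speed_curves[r, ] <- pmax(speed_curves[r, ], 0)
  }
  list(trials = tab, speed_curves = speed_curves, knee_curves = knee_curves)
}
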