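---
title: "Markerless dive kinematics: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless dive kinematics: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divekin)
```

divekin analyzes soccer goalkeepers' penalty dives recorded by multiple
synchronized video cameras and processed by a markerless pose estimator.
The input is, per camera, a time series of the 25 BODY_25 image-plane
keypoints with detection confidences; the output is per-trial dive
kinematics (six outcome variables and two normalized curves) and the
study-level statistics used to compare groups, conditions and dive sides.
This vignette explains each stage's model and assumptions, the parameters
that matter, the numerical choices, and what the synthetic-data validation
does and does not establish.

## World frame and conventions

All 3D quantities live in a field-fixed right-handed frame: X
anteroposterior (positive toward the penalty mark), Y mediolateral
(positive toward the goalkeeper's left), Z vertical, origin at the centre
of the goal line on the ground. Frames are indexed from 0, matching
pose-estimator file numbering. The default sampling rate is 120 Hz.

## Gap repair

Markerless detections drop out (confidence 0) or degrade. `fill_gaps()`
treats any sample below `conf_min` (default 0.1) as missing and replaces
it by piecewise-linear interpolation between the nearest valid flanking
frames, holding end gaps at the nearest valid value. Repairs are flagged
with confidence -1 and logged. A gap longer than `max_gap` frames
(default 12, i.e. 0.1 s at 120 Hz) cannot be repaired credibly at dive
dynamics and flags the trial unusable; the pipeline converts that flag
into a discarded trial with reason `"gap"`. Both limits are pragmatic
defaults for 120 Hz dive footage: 0.1 s is roughly the duration over
which a limb trajectory during the impulse is still near-linear.

## Camera model: 11-parameter DLT

Calibration uses the direct linear transformation: 11 coefficients per
camera map world coordinates (m) to image coordinates (px) as a ratio of
affine forms. `calibrate_dlt()` solves the standard linear least-squares
system from at least 6 surveyed control points; the goal frame (7.32 m x
2.44 m) plus back-frame depth points provides a natural control volume.
Because DLT needs volume, a coplanarity guard rejects control sets whose
centred coordinates have a smallest-to-largest singular-value ratio below
1e-3. `reconstruct_3d()` (and its vectorized form `reconstruct_points()`)
triangulates from two or more views by stacked linearized DLT equations;
a camera with a missing observation is simply dropped, which reproduces
the practice of falling back to the remaining cameras when one view
fails. No lens-distortion model is fitted: action cameras at field
distances are treated as ideal pinholes, and the self-reconstruction
error of the control points (mean absolute error per axis) is the honest
summary of what the rig delivers. Short-baseline frontal rigs inflate the
depth (X) axis error, the familiar anisotropy of goal-frame calibrations.

## Smoothing: zero-lag Butterworth with residual analysis

Coordinates are smoothed with a 2nd-order low-pass Butterworth filter
applied forward and backward — net 4th order with zero phase lag, the
standard biomechanics convention. The design cutoff is divided by the
dual-pass correction factor `(2^(1/2)-1)^(1/4) ~ 0.802` so the -3 dB
point of the combined response sits at the nominal cutoff (default 7 Hz).
Filtering is applied to the 2D image coordinates before reconstruction,
matching the conventional processing order; linearity of DLT
reconstruction in the observations makes the choice of filtering 2D
versus 3D nearly equivalent in practice.

Two numerical choices matter and were set after explicit experiments:

* **Edge handling.** The padded series is filtered from a zero state
  after removing its initial value, with odd-reflection padding of length
  `max(3 * order, 3 * fs / fc)` samples. Short pads leave a large
  zero-state transient at image-coordinate magnitudes (hundreds of
  pixels) that corrupts the first ~0.2 s of the filtered series.
* **Transient trim.** Even with correct padding, the first and last
  samples of a zero-lag filtered noisy series carry roughly twice the
  interior noise. `run_trial()` therefore trims `trim_s` (default
  0.15 s) from each end after smoothing and renumbers frames from 0,
  recording the trim in its QC block. This is the in-code equivalent of
  recording a margin around the movement and discarding it.

`residual_analysis_cutoff()` implements the classic residual analysis:
RMS residuals between raw and filtered series over a cutoff grid, a
straight line fitted to the noise-dominated upper 40% of the grid,
projected to 0 Hz to estimate the noise floor, and the selected cutoff at
the crossing. A noiseless series returns the top of the grid flagged
`no_noise_floor`; a curve with no crossing falls back to the configured
default with a warning.

## Segmental centre of mass

The whole-body CM uses the segmental method: 14 segments (head, trunk,
and paired upper arms, forearms, hands, thighs, shanks, feet), each with
a mass fraction and a CM position ratio along its proximal-to-distal
axis. The shipped table uses de Leva-style standardized fractions; mass
fractions sum to 1 exactly. BODY_25 provides no head vertex or hand tip,
so the head segment runs neck-to-nose with its CM at the midpoint and
hands are point masses at the wrists — both proxies are visible, documented
rows of a plain CSV that users can replace (`validate_anthropometric_table()`
checks any substitute). Body mass scales only the reported segment
masses, never the CM position. CM velocity is a central finite difference
(one-sided at the ends); the resultant speed is the Euclidean norm.

The knee angle is the interior 3D angle at the knee between the
knee-to-hip and knee-to-ankle vectors (180 degrees = full extension). Whether
published flexion/extension curves plot this angle or its supplement is
not always stated; the supplement is available via `convention = "flexion"`.

## Dive cycle and events

The dive impulse cycle runs from the first frame the ipsilateral foot
leaves the ground (`t_start`) to the frame of peak resultant CM velocity
(`t_prv`). Ground contact is decided from landmark heights: the foot is
"off" when both heel and big toe sit above `ground_z + eps` (default
eps = 0.03 m) for at least `k` consecutive frames (default 3); `ground_z`
is estimated per trial as the 5th percentile of foot-landmark heights
over the standing phase. The threshold rule is a declared substitute for
whatever manual criterion a human annotator applies; it is validated only
on synthetic data, where it recovers events exactly at zero noise.

PRV is searched from `t_start` to the last ipsilateral contact plus 6
frames (50 ms at 120 Hz) — the short lookahead admits the peak that occurs
just after the foot leaves while excluding the later free-fall portion,
whose speed is gravity's contribution rather than the goalkeeper's
impulse. Ties break to the first frame. Curves are time-normalized onto
101 nodes (0-100% in 1% steps) by linear interpolation, the grid that
curve-level inference conventions expect.

The six outcome variables:

* **PRV** (m/s): the windowed maximum resultant CM speed.
* **TRPRV** (s): `(t_prv - t_start) / fs`.
* **FSD** (m): anteroposterior big-toe displacement between first
  foot-off and the final departure, signed toward the penalty mark.
* **DBLPP** (ratio of leg length): heel-to-heel distance at the start of
  the final ipsilateral contact period, over the leg length measured as
  hip-knee plus knee-to-(ankle extrapolated to heel height). Stored as a
  ratio (published group values are ~0.73-0.80); multiply by 100 for the
  percentage rendering.
* **FDA** (degrees): horizontal-plane angle of the CM displacement between the
  first and last ipsilateral contact frames, measured from the
  mediolateral axis, so 0 is parallel to the goal line and the
  instructional target is 18. The vertical CM component is deliberately
  excluded: the angle's geometric rationale (shortest path to the ball's
  trajectory) is a ground-plane argument; the code isolates the
  definition so a sagittal variant can be swapped in.
* **Knee angle curve** (degrees): the ipsilateral interior knee angle on the
  101-node grid.

FSD's endpoint deserves a note: "the last moment the foot leaves the
ground" is ambiguous between the step landing and the final departure;
the implementation uses the first frame of the final off-period, and the
two-phase (step, then jump) synthetic pattern regression-tests that
reading.

## Statistics

**Cohen's d** uses the equal-weight pooled SD,
`|m1 - m2| / sqrt((s1^2 + s2^2)/2)` — the convention verified to reproduce
published dive-kinematics effect sizes from their group tables to two
decimals.

**Curve-level inference** is a 1D SPM paired t test with permutation
(sign-flip) inference rather than random-field theory: node-wise paired
t, critical threshold at the 95th percentile of the permutation
distribution of the maximum |t| over the cycle, and cluster p values from
the permutation distribution of the largest suprathreshold cluster
extent. Sign flips are enumerated exhaustively whenever `2^n` fits the
permutation budget, making the inference exact and fully reproducible.
Trials are averaged per goalkeeper and condition first, so the pairing
unit is the subject. A hard small-sample fact follows: with n paired
units the smallest attainable family-wise p is `2 / 2^n`, so with 4
subjects per group (the study-shaped cohort) within- and between-group
curve comparisons cannot reach 0.05 — only the laterality comparison
(n = 8) can. The between-group "pairing" by within-group position is a
stand-in for a two-sample curve test and is labelled as such in the
report.

**Scalar group effects** use a balanced mixed-design two-way
repeated-measures ANOVA (between: group; within: condition) on
subject-level means, with the four conventional cell contrasts
(pre-post within each group, between groups at each condition)
Bonferroni-adjusted within the family of four. `significant_findings()`
additionally offers a battery-wide Bonferroni screen across every
contrast in a report, which is what the null-cohort validation uses.
Laterality is a paired t across all eight goalkeepers with Cohen's d.

## The synthetic dive generator

`generate_dive_3d()` builds a 25-landmark motion with every downstream
quantity known by construction:

* the whole-body CM follows an analytic target path: a resultant-speed
  ramp — a truncated raised cosine that still rises into the peak (the
  push-off ends at the peak, so a velocity kink there is the physically
  sensible shape) — of prescribed peak (`peak_speed`, default 3 m/s) and
  duration (`impulse_duration`, default 0.55 s), directed along the
  prescribed departure azimuth (`departure_angle`, default 18 degrees) with a
  small constant elevation, plus a squat;
* feet are prescribed in world coordinates: planted, stepping
  (`step_length`, default 0.45 m, with a lateral drift solved so the
  heel separation at the step landing equals `stance_ratio x leg_length`,
  default 0.75 x 0.88 m), and departing with a fast vertical snap-up and
  a slow horizontal follow so event thresholds trigger within one frame
  of the construction;
* the pelvis translation is solved per frame by fixed-point iteration so
  the segmental CM of the generated landmarks reproduces the target path
  to ~1e-10 m, and knees are posed by two-link inverse kinematics, with
  the squat depth adapted (a few rebuild iterations) until the deepest
  ipsilateral knee angle during the impulse stance matches
  `knee_min_angle` (default 110 degrees) within ~1 degree.

Ground truth is then *recomputed from the generated trajectory by the
package's own definitions*, which makes it self-consistent; the spec
parameters are honored to the tolerances the tests assert (exact for
FSD/FDA/DBLPP/TRPRV at the frame grid; PRV to ~0.5% through the discrete
derivative). `render_views()` projects the trajectory through DLT cameras
built from pinhole parameters (`make_camera_rig()`, preset: one frontal
and two diagonal views), adds i.i.d. Gaussian pixel noise, and emits
dropouts and behind-camera points as confidence-0 keypoints.

What passing these validations shows: the pipeline's geometry, filtering,
event logic and statistics are internally correct and recover known
ground truth through the full chain, including under pixel noise
(documented envelope at 2 px: FSD within 0.03 m, FDA within 2 degrees, PRV
within 5%). What it does not show: robustness to the failure modes of
real markerless detection — identity swaps, systematic landmark bias
(e.g. heel placed on the boot), soft-tissue and clothing artifacts,
rolling-shutter and synchronization error, lens distortion. The generator
emulates none of these, so field deployments should still inspect repair
logs, self-reconstruction errors and QC flags per trial.

`generate_cohort()` produces a study-shaped dataset (2 groups x 4
goalkeepers x pre/post x both sides, 4 trials per cell) of outcome
variables and normalized curves from a subject-random-intercept model
around realistic field values, with optional injected shifts (a
video-instruction response in the video group post condition, a
laterality effect) so the statistical battery can be exercised with known
signal. It draws outcomes directly rather than rendering 128 full video
trials; the single-trial chain is validated separately, and the cohort
level is about the statistics.

Typical problem sizes used throughout the validation suite: 101-node
curves, 8 pairing units (256 exhaustive sign flips), 1000 null cohorts
for the false-positive-rate check, 50 generated dives for event/variable
recovery, 20 rendered noise seeds, 1000 random points for the DLT round
trip.

## Degenerate inputs and tie-breaks

Constant speed curves take the first frame at the maximum (PRV
tie-break). Zero-length thigh or shank vectors raise an undefined-angle
error naming the frame. Identical curve sets give a zero t curve and no
clusters. All-equal ANOVA data reports F = 0, p = 1 rather than 0/0. A CM
path with less than 0.2 m net mediolateral displacement is an ambiguous
dive side and discards the trial. Trials whose noisy speed argmax
collides with the last-contact frame violate the cycle ordering
`t_start <= t_last_contact < t_prv <= t_last_contact + 6` and are
discarded with reason `bad_cycle` — at 2 px noise this affects a small,
seed-dependent fraction of rendered trials, the in-silico analogue of the
field practice of discarding unusable attempts.

## Known limitations

* Camera synchronization is assumed: frame indices are taken as aligned
  across cameras. Synchronizing from content is out of scope.
* No lens-distortion or bundle-adjustment refinement of the DLT models.
* Permutation SPM at 4 subjects per group cannot reach 0.05 (see above);
  conclusions at that design size rest on the scalar contrasts.
* The anthropometric proxies for head and hands bias the CM by a few
  millimetres relative to a full marker set; they are consistent between
  generator and analysis, so validation is unaffected, but absolute CM
  positions on real data inherit the proxy.

## A worked example

```{r example, eval = FALSE}
library(divekin)

# ground-truth dive, rendered through three cameras at 1 px noise
g <- generate_dive_3d(synthetic_dive_spec(side = "left"))
rig <- make_camera_rig()
views <- render_views(g$trajectory, rig$cameras, noise_px = 1, seed = 1)

trial <- run_trial(views, rig$cameras, trial_config())
trial$variables
trial$cycle

# study-shaped cohort with an injected instruction effect on step length
cohort <- generate_cohort(effects = list(vg_post = list(fsd = 0.45)), seed = 11)
report <- run_study(cohort$trials, cohort$speed_curves, cohort$knee_curves,
                    seed = 3)
report
significant_findings(report)
```
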