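#' Zero-lag low-pass Butterworth filter
#'
#' Applies a 2nd-order low-pass Butterworth filter forward and backward
#' (net 4th order, zero phase shift), the dominant convention for
#' biomechanics coordinate data. The design cutoff is corrected by the
#' dual-pass factor \eqn{C = (2^{1/2} - 1)^{1/4} \approx 0.802} so the
#' -3 dB point of the combined response sits at `fc`. Edges are handled by
#' odd reflection padding of length `3 * order_net` samples.
#'
#' @param x numeric series with no missing values (gap-fill first).
#' @param fc cutoff frequency (Hz), default 7 as selected by residual
#'   analysis for 120 Hz dive recordings.
#' @param fs sampling rate (Hz).
#' @param order_net net (dual-pass) filter order; must be even. Default 4.
#' @return filtered series, same length as `x`.
#' @export
butter_lowpass_zerolag <- function(x, fc = 7, fs, order_net = 4L) {
  if (order_net %% 2L != 0L || order_net < 2L)
    stop("order_net must be a positive even integer")
  n1 <- order_net / 2L                      # single-pass order
  if (!(fc > 0 && fc < fs / 2)) stop("fc must lie in (0, fs/2)")
  n <- length(x)
  if (n <= 6L * order_net)
    stop(sprintf("series too short to filter: need > %d samples, got %d",
                 6L * order_net, n))
  if (anyNA(x)) stop("series contains missing values; gap-fill before filtering")
  corr <- (2^(1 / 2) - 1)^(1 / (2 * n1))    # dual-pass cutoff correction
  fc_design <- fc / corr
  if (fc_design >= fs / 2)
    stop(sprintf("corrected design cutoff %.2f Hz reaches the Nyquist frequency", fc_design))
  bf <- signal::butter(n1, 2 * fc_design / fs, type = "low")
  # reflection padding long enough for the zero-state filter transient to
  # settle before the series proper begins (a few filter time constants)
  p <- max(3L * order_net, min(n - 1L, ceiling(3 * fs / fc)))
  head_pad <- 2 * x[1L] - x[(p + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
  xp <- c(head_pad, x, tail_pad)
  x0 <- xp[1L]                 # zero-state start: filter the deviation signal
  y <- as.numeric(signal::filter(bf, xp - x0)) + x0
  yr <- rev(y)
  y0 <- yr[1L]
  y <- rev(as.numeric(signal::filter(bf, yr - y0)) + y0)
  y[(p + 1L):(p + n)]
}

#' Automatic cutoff selection by residual analysis
#'
#' Winter's residual-analysis procedure: the RMS residual between the raw
#' and filtered series is computed over a grid of candidate cutoffs; a
#' straight line is fitted to the residuals over the high-frequency
#' (noise-dominated) tail of the grid and projected to 0 Hz to estimate
#' the noise floor; the selected cutoff is where the residual curve meets
#' that floor.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param fc_grid candidate cutoffs (Hz), >= 10 points inside (0, fs/2).
#' @param tail_frac fraction of the grid (uppermost cutoffs) used for the
#'   noise-line fit. Default 0.4.
#' @param default_fc fallback cutoff when the residual curve admits no
#'   intersection with the noise line. Default 7 Hz.
#' @param order_net passed to [butter_lowpass_zerolag()].
#' @return selected cutoff (Hz) with attribute `"flag"` (`"ok"`,
#'   `"no_noise_floor"` when nothing needs removing and the top of the
#'   grid is returned, or `"fallback"`), plus attribute `"residuals"`
#'   holding the residual curve for inspection.
#' @export
residual_analysis_cutoff <- function(x, fs, fc_grid = seq(1, 15, by = 0.5),
                                     tail_frac = 0.4, default_fc = 7,
                                     order_net = 4L) {
  fc_grid <- sort(fc_grid)
  if (length(fc_grid) < 10L) stop("fc_grid must hold >= 10 candidate cutoffs")
  if (fc_grid[1L] <= 0 || fc_grid[length(fc_grid)] >= fs / 2)
    stop("fc_grid must lie inside (0, fs/2)")
  res <- vapply(fc_grid, function(fc)
    sqrt(mean((x - butter_lowpass_zerolag(x, fc, fs, order_net))^2)), 0)
  m <- length(fc_grid)
  tail_idx <- seq.int(ceiling((1 - tail_frac) * m) + 1L, m)
  if (length(tail_idx) < 2L) tail_idx <- c(m - 1L, m)
  fit <- stats::lm.fit(cbind(1, fc_grid[tail_idx]), res[tail_idx])
  noise_floor <- fit$coefficients[1L]       # projection of noise line to 0 Hz
  out <- function(fc, flag) {
    structure(fc, flag = flag,
              residuals = data.frame(fc = fc_grid, rms_residual = res))
  }
  if (res[m] < 1e-3 * stats::sd(x))   # essentially noiseless: nothing to remove
    return(out(fc_grid[m], "no_noise_floor"))
  if (noise_floor <= 0 || !is.finite(noise_floor)) {
    if (all(diff(res) <= 1e-12) || res[m] <= 1e-12)
      return(out(fc_grid[m], "no_noise_floor"))
    warning(sprintf(
      "residual curve admits no noise-line intersection; falling back to %g Hz", default_fc))
    return(out(default_fc, "fallback"))
  }
  below <- which(res <= noise_floor)
  if (length(below) == 0L) return(out(fc_grid[m], "no_noise_floor"))
  i <- below[1L]
  if (i == 1L) {
    fc_sel <- fc_grid[1L]
  } else {
    # linear interpolation of the crossing between the bracketing grid points
    fc_sel <- fc_grid[i - 1L] + (fc_grid[i] - fc_grid[i - 1L]) *
      (res[i - 1L] - noise_floor) / (res[i - 1L] - res[i])
  }
  out(fc_sel, "ok")
}

## filter every keypoint coordinate of a pose sequence (2D smoothing,
## applied before reconstruction as in the standard processing order)
smooth_pose_sequence <- function(seq, fc = 7, order_net = 4L) {
  u <- seq$u; v <- seq$v
  for (j in seq_len(N_KEYPOINTS)) {
    u[, j] <- butter_lowpass_zerolag(u[, j], fc, seq$fs, order_net)
    v[, j] <- butter_lowpass_zerolag(v[, j], fc, seq$fs, order_net)
  }
  out <- pose_sequence(seq$camera_id, seq$fs, u, v, seq$conf, seq$frame_index)
  attr(out, "repairs") <- attr(seq, "repairs")
  out
}
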