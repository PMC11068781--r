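#' Construct an 11-coefficient DLT camera
#'
#' The direct linear transformation maps a world point (metres, field
#' frame) to image coordinates (pixels):
#' \deqn{u = \frac{L_1 X + L_2 Y + L_3 Z + L_4}{L_9 X + L_{10} Y + L_{11} Z + 1},\qquad
#'       v = \frac{L_5 X + L_6 Y + L_7 Z + L_8}{L_9 X + L_{10} Y + L_{11} Z + 1}.}
#'
#' @param camera_id camera label.
#' @param L numeric vector of exactly 11 DLT coefficients.
#' @return an object of class `dlt_camera`.
#' @export
dlt_camera <- function(camera_id, L) {
  L <- as.numeric(L)
  if (length(L) != 11L) stop("a DLT camera has exactly 11 coefficients")
  structure(list(camera_id = as.character(camera_id), L = L),
            class = "dlt_camera")
}

#' @export
print.dlt_camera <- function(x, ...) {
  cat(sprintf("<dlt_camera> '%s' L = [%s]\n", x$camera_id,
              paste(signif(x$L, 5), collapse = ", ")))
  invisible(x)
}

#' Calibrate a camera by linear DLT from surveyed control points
#'
#' Solves the standard linear DLT least-squares system built from >= 6
#' non-coplanar control points with known 3D coordinates and observed
#' image positions. The control-point reprojection RMSE (px) is attached
#' as attribute `"rmse_px"`.
#'
#' @param xyz n x 3 matrix of world coordinates (m).
#' @param uv n x 2 matrix of observed image coordinates (px).
#' @param camera_id camera label.
#' @param coplanarity_tol degeneracy guard: calibration aborts when the
#'   ratio of smallest to largest singular value of the centred control
#'   coordinates falls below this value (the points then span no volume).
#' @return a [dlt_camera()] with attribute `rmse_px`.
#' @export
calibrate_dlt <- function(xyz, uv, camera_id = "cam", coplanarity_tol = 1e-3) {
  xyz <- as.matrix(xyz); uv <- as.matrix(uv)
  n <- nrow(xyz)
  if (n < 6L)
    stop_divekin(sprintf("DLT calibration needs >= 6 control points, got %d", n),
                 "divekin_insufficient_points")
  if (nrow(uv) != n || ncol(xyz) != 3L || ncol(uv) != 2L)
    stop("xyz must be n x 3 and uv n x 2 with matching n")
  sv <- svd(scale(xyz, center = TRUE, scale = FALSE))$d
  if (sv[3L] / sv[1L] < coplanarity_tol)
    stop_divekin(sprintf(
      "control points are near-coplanar (singular-value ratio %.2e < %.0e); DLT geometry degenerate",
      sv[3L] / sv[1L], coplanarity_tol), "divekin_degenerate_geometry")
  X <- xyz[, 1L]; Y <- xyz[, 2L]; Z <- xyz[, 3L]
  u <- uv[, 1L]; w <- uv[, 2L]
  zero <- numeric(n); one <- rep(1, n)
  A <- rbind(
    cbind(X, Y, Z, one, zero, zero, zero, zero, -u * X, -u * Y, -u * Z),
    cbind(zero, zero, zero, zero, X, Y, Z, one, -w * X, -w * Y, -w * Z))
  b <- c(u, w)
  L <- qr.solve(A, b)
  cam <- dlt_camera(camera_id, L)
  pred <- dlt_project(cam, xyz)
  attr(cam, "rmse_px") <- sqrt(mean((pred - uv)^2))
  cam
}

#' Project world points through a DLT camera
#'
#' Forward DLT model; vectorized over points.
#'
#' @param camera a [dlt_camera()].
#' @param xyz a length-3 vector or an n x 3 matrix of world points (m).
#' @param on_behind what to do when the DLT denominator is not positive
#'   (point behind the camera plane): `"error"` or `"na"`.
#' @return an n x 2 matrix of image coordinates (px).
#' @export
dlt_project <- function(camera, xyz, on_behind = c("error", "na")) {
  on_behind <- match.arg(on_behind)
  stopifnot(inherits(camera, "dlt_camera"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
  xyz <- as.matrix(xyz)
  L <- camera$L
  den <- xyz %*% L[9:11] + 1
  bad <- den <= 0
  if (any(bad)) {
    if (on_behind == "error")
      stop_divekin(sprintf("%d point(s) behind camera '%s' (non-positive DLT denominator)",
                           sum(bad), camera$camera_id), "divekin_behind_camera")
    den[bad] <- NA_real_
  }
  u <- (xyz %*% L[1:3] + L[4]) / den
  v <- (xyz %*% L[5:7] + L[8]) / den
  cbind(u = as.vector(u), v = as.vector(v))
}

#' Triangulate a 3D point from two or more camera observations
#'
#' Least-squares solution of the stacked linearized DLT equations. With
#' more than two cameras all observations are used. Cameras whose
#' observation is `NA` are skipped, which implements the study's fallback
#' of reconstructing from the remaining views when one camera fails.
#'
#' @param cameras list of [dlt_camera()].
#' @param uv n_cameras x 2 matrix of observed image coordinates (px);
#'   use `NA` rows for missing observations.
#' @return length-3 world point (m) with attribute `residual_px`
#'   (RMS of the stacked linear-equation residuals).
#' @export
reconstruct_3d <- function(cameras, uv) {
  uv <- matrix(as.numeric(uv), ncol = 2L)
  ok <- stats::complete.cases(uv)
  if (sum(ok) < 2L)
    stop_divekin(sprintf("3D reconstruction needs >= 2 camera observations, got %d", sum(ok)),
                 "divekin_insufficient_views")
  A <- matrix(0, 2L * sum(ok), 3L); b <- numeric(2L * sum(ok))
  r <- 0L
  for (i in which(ok)) {
    L <- cameras[[i]]$L
    u <- uv[i, 1L]; v <- uv[i, 2L]
    A[r + 1L, ] <- c(L[1] - u * L[9], L[2] - u * L[10], L[3] - u * L[11])
    A[r + 2L, ] <- c(L[5] - v * L[9], L[6] - v * L[10], L[7] - v * L[11])
    b[r + 1L] <- u - L[4]
    b[r + 2L] <- v - L[8]
    r <- r + 2L
  }
  p <- qr.solve(A, b)
  structure(as.vector(p), residual_px = sqrt(mean((A %*% p - b)^2)))
}

#' Triangulate many points at once
#'
#' Vectorized form of [reconstruct_3d()]: solves the per-point 3x3 normal
#' equations of the stacked linearized DLT system in closed form (Cramer's
#' rule) across an entire coordinate series, which is what the trial
#' pipeline uses frame by frame. `NA` observations are skipped per point;
#' points visible in fewer than two cameras come back `NA`.
#'
#' @param cameras list of [dlt_camera()].
#' @param u_list,v_list one numeric vector per camera (length = number of
#'   points) of image coordinates (px).
#' @param w_list optional per-camera 0/1 usage weights, same shape.
#' @return points x 3 matrix of world coordinates (m).
#' @export
reconstruct_points <- function(cameras, u_list, v_list, w_list = NULL) {
  ncam <- length(cameras)
  npts <- length(u_list[[1L]])
  if (is.null(w_list))
    w_list <- rep(list(rep(1, npts)), ncam)
  a11 <- a12 <- a13 <- a22 <- a23 <- a33 <- numeric(npts)
  b1 <- b2 <- b3 <- numeric(npts)
  nview <- numeric(npts)
  for (i in seq_len(ncam)) {
    L <- cameras[[i]]$L
    u <- u_list[[i]]; v <- v_list[[i]]
    w <- w_list[[i]] * !is.na(u) * !is.na(v)
    u[is.na(u)] <- 0; v[is.na(v)] <- 0
    nview <- nview + w
    g1 <- L[1] - u * L[9]; g2 <- L[2] - u * L[10]; g3 <- L[3] - u * L[11]
    h1 <- L[5] - v * L[9]; h2 <- L[6] - v * L[10]; h3 <- L[7] - v * L[11]
    cu <- u - L[4]; cv <- v - L[8]
    a11 <- a11 + w * (g1 * g1 + h1 * h1)
    a12 <- a12 + w * (g1 * g2 + h1 * h2)
    a13 <- a13 + w * (g1 * g3 + h1 * h3)
    a22 <- a22 + w * (g2 * g2 + h2 * h2)
    a23 <- a23 + w * (g2 * g3 + h2 * h3)
    a33 <- a33 + w * (g3 * g3 + h3 * h3)
    b1 <- b1 + w * (g1 * cu + h1 * cv)
    b2 <- b2 + w * (g2 * cu + h2 * cv)
    b3 <- b3 + w * (g3 * cu + h3 * cv)
  }
  det <- a11 * (a22 * a33 - a23 * a23) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  det[nview < 2] <- NA_real_
  x <- (b1 * (a22 * a33 - a23 * a23) - a12 * (b2 * a33 - a23 * b3) +
          a13 * (b2 * a23 - a22 * b3)) / det
  y <- (a11 * (b2 * a33 - a23 * b3) - b1 * (a12 * a33 - a23 * a13) +
          a13 * (a12 * b3 - b2 * a13)) / det
  z <- (a11 * (a22 * b3 - b2 * a23) - a12 * (a12 * b3 - b2 * a13) +
          b1 * (a12 * a23 - a22 * a13)) / det
  cbind(x, y, z)
}

#' Self-reconstruction error of a calibrated rig
#'
#' Reconstructs every control point from its own image observations and
#' returns the mean absolute error per world axis, the accuracy report
#' conventionally quoted for goal-frame calibrations.
#'
#' @param cameras list of [dlt_camera()].
#' @param xyz n x 3 control-point world coordinates (m).
#' @param uv_per_camera list (one n x 2 matrix per camera) of observed
#'   image coordinates; `NA` rows mark points unseen by that camera.
#' @return named numeric vector `c(X=, Y=, Z=)` of mean absolute errors (m),
#'   with the full n x 3 reconstruction as attribute `"reconstructed"`.
#' @export
self_reconstruction_error <- function(cameras, xyz, uv_per_camera) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  rec <- matrix(NA_real_, n, 3L)
  for (p in seq_len(n)) {
    uv <- do.call(rbind, lapply(uv_per_camera, function(m) m[p, , drop = TRUE]))
    rec[p, ] <- reconstruct_3d(cameras, uv)
  }
  err <- colMeans(abs(rec - xyz))
  names(err) <- c("X", "Y", "Z")
  attr(err, "reconstructed") <- rec
  err
}
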