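# shared fixtures, built in code

# a known synthetic camera: pure scaling plus principal point, no
# perspective denominators (L9 = L10 = L11 = 0)
affine_camera <- function(id = "affine", f = 100, cx = 500, cy = 400) {
  dlt_camera(id, c(f, 0, 0, cx, 0, f, 0, cy, 0, 0, 0))
}

# non-coplanar control points spanning a goal-sized volume
volume_control_points <- function() {
  as.matrix(expand.grid(x = c(-1.5, 0, 1), y = c(-3, 0, 3), z = c(0, 1.2, 2.4)))
}

random_volume_points <- function(n, seed = 1) {
  set.seed(seed)
  cbind(runif(n, -1.2, 2.0), runif(n, -3.3, 3.3), runif(n, 0.05, 2.3))
}

# default dive + rig, generated once per test run
default_dive <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dive_3d(synthetic_dive_spec())
    cache
  }
})

default_rig <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_camera_rig()
    cache
  }
})

# a minimal standing pose: all 25 landmarks at plausible static positions
static_pose_array <- function(n_frames = 30) {
  g <- default_dive()
  pos <- g$trajectory$positions[rep(1L, n_frames), , , drop = FALSE]
  pos
}

# brute-force segmental CM: explicit loop over segments (oracle)
cm_bruteforce <- function(pos_frame, table) {
  cm <- c(0, 0, 0)
  for (s in seq_len(nrow(table))) {
    p <- pos_frame[table$proximal_id[s] + 1L, ]
    d <- pos_frame[table$distal_id[s] + 1L, ]
    seg <- p + table$cm_ratio[s] * (d - p)
    cm <- cm + table$mass_fraction[s] * seg
  }
  cm
}
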