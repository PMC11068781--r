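test_that("JSON directory round trip preserves coordinates and frame order", {
  g <- default_dive()
  rig <- default_rig()
  views <- render_views(g$trajectory, rig$cameras, noise_px = 1,
                        dropout_rate = 0.05, seed = 4)
  d <- withr::local_tempdir()
  write_pose_sequence(views[[1]], d)
  back <- read_pose_sequence(d, views[[1]]$camera_id, fs = 120)
  expect_equal(nrow(back$u), nrow(views[[1]]$u))
  expect_equal(back$frame_index, views[[1]]$frame_index)
  expect_lt(max(abs(back$u - views[[1]]$u)), 1e-9)
  expect_lt(max(abs(back$v - views[[1]]$v)), 1e-9)
  expect_equal(back$conf, views[[1]]$conf, tolerance = 1e-12)
})

test_that("consolidated CSV round trip preserves coordinates", {
  g <- default_dive()
  views <- render_views(g$trajectory, default_rig()$cameras, noise_px = 0.5,
                        seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(views[[2]], f)
  back <- read_pose_sequence(f, "cam2")
  expect_lt(max(abs(back$u - views[[2]]$u)), 1e-9)
  expect_lt(max(abs(back$v - views[[2]]$v)), 1e-9)
})

test_that("frames with no detected person become all-zero-confidence frames", {
  d <- withr::local_tempdir()
  flat <- as.vector(rbind(runif(25, 0, 100), runif(25, 0, 100), rep(0.9, 25)))
  jsonlite::write_json(list(version = 1.3,
                            people = list(list(pose_keypoints_2d = flat))),
                       file.path(d, "c_000000000000_keypoints.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(version = 1.3, people = list()),
                       file.path(d, "c_000000000001_keypoints.json"),
                       auto_unbox = TRUE, digits = NA)
  s <- read_pose_sequence(d, "c")
  expect_equal(nrow(s$u), 2L)
  expect_true(all(s$conf[2, ] == 0))
  expect_true(all(s$conf[1, ] == 0.9))
})

test_that("the person with the highest mean confidence is kept, with a log", {
  d <- withr::local_tempdir()
  p1 <- as.vector(rbind(rep(1, 25), rep(2, 25), rep(0.3, 25)))
  p2 <- as.vector(rbind(rep(7, 25), rep(8, 25), rep(0.8, 25)))
  jsonlite::write_json(
    list(version = 1.3, people = list(list(pose_keypoints_2d = p1),
                                      list(pose_keypoints_2d = p2))),
    file.path(d, "c_000000000000_keypoints.json"), auto_unbox = TRUE, digits = NA)
  expect_message(s <- read_pose_sequence(d, "c"), "2 people detected, kept person 2")
  expect_true(all(s$u[1, ] == 7))
})

test_that("malformed records raise a parse error naming the frame file", {
  d <- withr::local_tempdir()
  jsonlite::write_json(
    list(people = list(list(pose_keypoints_2d = 1:10))),
    file.path(d, "c_000000000003_keypoints.json"), auto_unbox = TRUE)
  expect_error(read_pose_sequence(d, "c"), "c_000000000003.*expected 75")
  writeLines("{not json", file.path(d, "c_000000000003_keypoints.json"))
  expect_error(read_pose_sequence(d, "c"), "malformed.*c_000000000003")
})

test_that("empty inputs raise an empty-input error", {
  d <- withr::local_tempdir()
  expect_error(read_pose_sequence(d, "c"), class = "divekin_empty_input")
})

test_that("fill_gaps interpolates single-frame gaps at the midpoint", {
  n <- 30
  u <- matrix(1, n, 25); v <- matrix(2, n, 25); conf <- matrix(0.9, n, 25)
  u[, 3] <- seq_len(n); v[, 3] <- 2 * seq_len(n)
  conf[11, 3] <- 0           # frame index 10 missing (0-based)
  u[11, 3] <- -999; v[11, 3] <- -999
  s <- fill_gaps(pose_sequence("c", 120, u, v, conf))
  expect_equal(s$u[11, 3], (u[10, 3] + u[12, 3]) / 2)
  expect_equal(s$v[11, 3], (v[10, 3] + v[12, 3]) / 2)
  expect_equal(s$conf[11, 3], -1)
  expect_equal(attr(s, "repairs"),
               data.frame(frame = 10L, keypoint_id = 2L))
})

test_that("fill_gaps is an identity on fully valid sequences and idempotent", {
  g <- default_dive()
  views <- render_views(g$trajectory, default_rig()$cameras, seed = 1)
  s <- views[[1]]
  filled <- fill_gaps(s)
  expect_equal(filled$u, s$u)
  expect_equal(filled$conf, s$conf)
  noisy <- render_views(g$trajectory, default_rig()$cameras,
                        dropout_rate = 0.05, seed = 2)[[1]]
  once <- fill_gaps(noisy)
  twice <- fill_gaps(once)
  expect_identical(once$u, twice$u)
  expect_identical(once$v, twice$v)
  expect_equal(nrow(once$u), nrow(noisy$u))   # frame count preserved
})

test_that("fill_gaps repairs a noisy sinusoid track within an analytic bound", {
  # 1 Hz sinusoid sampled at 120 Hz with 5% random single-frame dropouts:
  # linear interpolation over one missing frame errs by at most
  # max|f''| * h^2 / 8 = (2*pi)^2 / (8 * 120^2) of the amplitude
  set.seed(7)
  n <- 600
  t <- (0:(n - 1)) / 120
  track <- 100 + 50 * sin(2 * pi * t)
  u <- matrix(1, n, 25); v <- matrix(1, n, 25); conf <- matrix(0.9, n, 25)
  u[, 5] <- track
  miss <- which(stats::rbinom(n - 2, 1, 0.05) == 1) + 1L
  miss <- miss[c(TRUE, diff(miss) > 1)]        # keep gaps single-frame
  conf[miss, 5] <- 0
  u[miss, 5] <- 0
  s <- fill_gaps(pose_sequence("c", 120, u, v, conf))
  # valid flanking samples sit 2 frames apart, so h = 2/120
  bound <- 50 * (2 * pi)^2 * (2 / 120)^2 / 8
  expect_lt(max(abs(s$u[miss, 5] - track[miss])), bound * 1.02)
})

test_that("gaps longer than max_gap flag the trial unusable", {
  n <- 60
  u <- matrix(1, n, 25); v <- matrix(1, n, 25); conf <- matrix(0.9, n, 25)
  conf[20:35, 8] <- 0       # 16-frame gap > 12
  expect_error(fill_gaps(pose_sequence("c", 120, u, v, conf)),
               class = "divekin_gap_error")
  expect_silent(fill_gaps(pose_sequence("c", 120, u, v, conf), max_gap = 16))
})

test_that("end gaps are held at the nearest valid value", {
  n <- 40
  u <- matrix(5, n, 25); v <- matrix(6, n, 25); conf <- matrix(0.9, n, 25)
  u[, 1] <- seq_len(n)
  conf[1:3, 1] <- 0; conf[38:40, 1] <- 0
  s <- fill_gaps(pose_sequence("c", 120, u, v, conf))
  expect_true(all(s$u[1:3, 1] == u[4, 1]))
  expect_true(all(s$u[38:40, 1] == u[37, 1]))
})
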