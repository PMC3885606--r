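test_that("frame detection finds worms and rejects round debris of equal area", {
  cfg <- sim_video_config(rep(1, 4), seed = 13, frame_size = c(300, 400),
                          n_frames = 10)
  v <- render_worm_video(cfg)
  regs <- detect_frame_objects(v$frames[[1]], tracker_params())
  expect_identical(nrow(regs), 4L)

  # one worm plus one round blob of comparable area
  img <- matrix(220, 200, 260)
  img[100:102, 40:79] <- 30                         # 120 px worm
  img[fix_disk_mask(c(200, 260), c(60, 180), 6)] <- 30  # ~113 px disk
  regs2 <- detect_frame_objects(gray_image(img), tracker_params())
  expect_identical(nrow(regs2), 1L)
  expect_gt(regs2$eccentricity, 0.9)

  blank <- gray_image(matrix(200, 120, 120))
  expect_identical(nrow(detect_frame_objects(blank, tracker_params())), 0L)
})

test_that("one worm in frame yields one complete track", {
  cfg <- sim_video_config(1, seed = 19, frame_size = c(240, 320),
                          n_frames = 30)
  v <- render_worm_video(cfg)
  res <- track_video(v, tracker_params())
  expect_identical(length(res$tracks), 1L)
  tr <- res$tracks[[1]]
  expect_identical(tr$end_reason, "video_end")
  expect_identical(length(tr$frames), 30L)
  expect_identical(nrow(tr$centroids), 30L)
})

test_that("a worm walking off the edge ends its track at the boundary", {
  w <- sim_worm(start = c(60, 250), heading = 0, speed = 3)
  cfg <- sim_config(list(w), frame_size = c(120, 320), n_frames = 40,
                    seed = 2)
  v <- render_worm_video(cfg)
  suppressWarnings(res <- track_video(v, tracker_params()))
  expect_identical(length(res$tracks), 1L)
  expect_identical(res$tracks[[1]]$end_reason, "boundary")
})

test_that("no region is ever claimed by two tracks", {
  cfg <- sim_video_config(rep(1, 5), seed = 23, frame_size = c(300, 400),
                          n_frames = 40)
  v <- render_worm_video(cfg)
  p <- tracker_params()
  frames <- lapply(v$frames, detect_frame_objects, p = p)
  tracks <- build_tracks(frames, p, frame_dim = c(300, 400))
  for (f in seq_along(frames)) {
    pts <- do.call(rbind, lapply(tracks, function(tr) {
      i <- match(f, tr$frames)
      if (is.na(i)) NULL else tr$centroids[i, , drop = FALSE]
    }))
    if (!is.null(pts) && nrow(pts) > 1)
      expect_identical(anyDuplicated(round(pts, 3)), 0L)
  }
})

test_that("smoothing reproduces collinear input and passes short input through", {
  t <- 0:20
  pts <- cbind(5 + 0.7 * t, 3 + 0.2 * t)
  sm <- smooth_track(pts)
  expect_identical(nrow(sm), nrow(pts))
  expect_lt(max(abs(sm - pts)), 0.5)

  two <- cbind(c(1, 2), c(3, 4))
  expect_identical(smooth_track(two), two)
})

test_that("smoothing shrinks noise and never lengthens straight-truth tracks", {
  set.seed(99)
  for (k in 1:10) {
    t <- 0:49
    truth <- cbind(10 + 0.8 * t, 20 + 0.3 * t)
    noisy <- truth + matrix(rnorm(100, 0, 1), ncol = 2)
    sm <- smooth_track(noisy)
    raw_len <- sum(sqrt(rowSums(diff(noisy)^2)))
    sm_len <- sum(sqrt(rowSums(diff(sm)^2)))
    expect_lte(sm_len, raw_len)
    expect_lt(sd(sm - truth), sd(noisy - truth))
  }
})

test_that("velocity arithmetic converts pixels per frame to micrometers per second", {
  tr <- structure(list(id = 1L, frames = 1:30,
                       centroids = cbind(rep(50, 30), 10 + 0:29),
                       areas = rep(120, 30), end_reason = "video_end"),
                  class = "worm_track")
  v <- track_velocity(tr, tracker_params(fps = 7, scale = 20, path_stride = 1))
  expect_equal(v$velocity_um_s, 140, tolerance = 1e-6)
  expect_true(v$included)
})

test_that("stationary trails are excluded from population statistics", {
  wiggle <- cbind(50 + sin(1:40), 80 + cos(1:40))
  tr <- structure(list(id = 1L, frames = 1:40, centroids = wiggle,
                       areas = rep(100, 40), end_reason = "video_end"),
                  class = "worm_track")
  v <- track_velocity(tr, tracker_params(stationary_box = 5))
  expect_false(v$included)
  s <- summarize_velocities(structure(list(tr), class = "track_set"),
                            tracker_params(stationary_box = 5))
  expect_true(s$empty)
  expect_identical(s$n_excluded, 1L)
})

test_that("population summaries average per-track velocities", {
  mk <- function(id, step) structure(
    list(id = id, frames = 1:30,
         centroids = cbind(rep(20 * id, 30), 10 + step * (0:29)),
         areas = rep(120, 30), end_reason = "video_end"),
    class = "worm_track")
  tracks <- structure(list(mk(1, 0.5), mk(2, 1), mk(3, 1.5)),
                      class = "track_set")
  s <- summarize_velocities(tracks, tracker_params(fps = 7, scale = 20,
                                                   path_stride = 1))
  expect_identical(s$n_tracks, 3L)
  expect_equal(s$mean, 140, tolerance = 1e-6)
  expect_equal(nrow(s$cumulative), 3L)
})

test_that("slow simulated worms are recovered within a few percent", {
  cfg <- sim_video_config(rep(0.25, 3), seed = 29, n_frames = 210)
  v <- render_worm_video(cfg)
  res <- track_video(v, tracker_params(fps = 7, scale = 20))
  tab <- res$summary$tracks
  expect_identical(nrow(tab), 3L)
  expect_true(all(abs(tab$speed_px_frame - 0.25) / 0.25 < 0.05))
})
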