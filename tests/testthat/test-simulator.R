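test_that("identical seed and config give bit-identical assets", {
  cfg <- sim_video_config(c(1, 0.5), seed = 5, frame_size = c(160, 200),
                          n_frames = 12)
  v1 <- render_worm_video(cfg)
  v2 <- render_worm_video(cfg)
  expect_identical(v1$frames, v2$frames)
  expect_identical(v1$truth, v2$truth)

  p1 <- render_egg_plate(12, 0.3, 4, seed = 8, canvas = c(200, 260))
  p2 <- render_egg_plate(12, 0.3, 4, seed = 8, canvas = c(200, 260))
  expect_identical(p1$image$pixels, p2$image$pixels)
  expect_identical(p1$truth$eggs, p2$truth$eggs)
})

test_that("a zero-speed worm undulates in place with a fixed centroid", {
  w <- sim_worm(start = c(80, 100), speed = 0, phase_rate = 0.5)
  cfg <- sim_config(list(w), frame_size = c(160, 200), n_frames = 20,
                    noise_sd = 0, seed = 3)
  v <- render_worm_video(cfg)
  tr <- v$trajectories[[1]]
  expect_equal(max(abs(tr[, 1] - 80)), 0)
  expect_equal(max(abs(tr[, 2] - 100)), 0)
  # posture still changes
  expect_false(identical(v$frames[[1]], v$frames[[10]]))
  # the pixel-area centroid may breathe slightly with the undulation
  # (pixel density varies with local slope) but must not drift
  cent <- t(vapply(v$frames, function(f) {
    idx <- which(f < 120, arr.ind = TRUE); colMeans(idx)
  }, numeric(2)))
  expect_lt(diff(range(cent[, 1])), 2)
  expect_lt(diff(range(cent[, 2])), 2)
})

test_that("constant-velocity kinematics hold over a video", {
  w <- sim_worm(start = c(80, 60), heading = 0, speed = 1)
  cfg <- sim_config(list(w), frame_size = c(160, 240), n_frames = 30,
                    noise_sd = 0, seed = 2)
  v <- render_worm_video(cfg)
  tr <- v$trajectories[[1]]
  expect_equal(unname(tr[30, "col"] - tr[1, "col"]), 29)
  expect_equal(unname(tr[30, "row"]), unname(tr[1, "row"]))
  # pixel centroid displacement matches within rasterization error
  cent <- t(vapply(v$frames, function(f) {
    idx <- which(f < 120, arr.ind = TRUE); colMeans(idx)
  }, numeric(2)))
  expect_lt(abs((cent[30, 2] - cent[1, 2]) - 29), 1)
})

test_that("regressing true centroids on frame index recovers configured speed", {
  for (sp in c(0.25, 1, 2)) {
    cfg <- sim_video_config(sp, seed = 17, frame_size = c(300, 400),
                            n_frames = 100)
    v <- render_worm_video(cfg)
    tr <- v$trajectories[[1]]
    t <- seq_len(nrow(tr)) - 1
    vr <- coef(lm(tr[, 1] ~ t))[2]
    vc <- coef(lm(tr[, 2] ~ t))[2]
    expect_lt(abs(sqrt(vr^2 + vc^2) - sp) / sp, 0.01)
  }
})

test_that("the two-cohort configuration matches the published video spec", {
  cfg <- movie_s1_config(seed = 6, n_frames = 20)
  expect_identical(length(cfg$worms), 20L)
  speeds <- vapply(cfg$worms, `[[`, numeric(1), "speed")
  expect_identical(sum(speeds == 1), 10L)
  expect_identical(sum(speeds == 0.25), 10L)
  expect_equal(cfg$fps, 7)
})

test_that("worms starting outside the frame are rejected", {
  w <- sim_worm(start = c(5, 5), speed = 1)
  cfg <- sim_config(list(w), frame_size = c(100, 100), n_frames = 5)
  expect_error(render_worm_video(cfg), "outside")
})

test_that("length plates record quadrature arc lengths and scale correctly", {
  p <- render_length_plate(3, length_range = c(220, 320), seed = 12,
                           canvas = c(520, 520), thickness = 5, scale = 20)
  expect_identical(nrow(p$truth), 3L)
  expect_true(all(p$truth$arc_length_px >= 220 & p$truth$arc_length_px <= 321))
  expect_equal(p$truth$arc_length_um, p$truth$arc_length_px * 20)

  # straight worms have arc length exactly the support length
  ps <- render_length_plate(1, length_range = c(150, 150), seed = 3,
                            canvas = c(300, 300), thickness = 5,
                            rel_amplitude_range = c(0, 0))
  expect_equal(ps$truth$arc_length_px, 150)

  pb <- render_length_plate(0, seed = 1, canvas = c(200, 200))
  expect_identical(nrow(pb$truth), 0L)
  expect_true(all(pb$image$pixels > 150))   # blank plate
})

test_that("egg plates honor count, clustering and debris bookkeeping", {
  p0 <- render_egg_plate(0, debris_count = 5, seed = 4, canvas = c(240, 300))
  expect_identical(p0$truth$n_eggs, 0)
  expect_identical(nrow(p0$truth$eggs), 0L)

  p <- render_egg_plate(30, cluster_fraction = 0, seed = 4,
                        canvas = c(400, 520))
  expect_identical(nrow(p$truth$eggs), 30L)
  d <- as.matrix(dist(cbind(p$truth$eggs$center_r, p$truth$eggs$center_c)))
  diag(d) <- Inf
  expect_gt(min(d), 12)    # all separated

  pc <- render_egg_plate(30, cluster_fraction = 0.4, seed = 9,
                         canvas = c(400, 520))
  expect_identical(nrow(pc$truth$eggs), 30L)
  expect_equal(sum(pc$truth$eggs$clustered), 12)
})

test_that("time-lapse pairs move only the movers", {
  p <- render_lifespan_pair(0, 10, seed = 5, canvas = c(500, 700),
                            noise_sd = 0)
  expect_identical(p$img1$pixels, p$img2$pixels)

  pm <- render_lifespan_pair(10, 0, displacement = 10, seed = 5,
                             canvas = c(600, 900), noise_sd = 0)
  d <- abs(pm$img1$pixels - pm$img2$pixels)
  comp <- label_regions(d > 50, 8)
  expect_gte(nrow(comp[comp$area > 20, ]), 10)

  p7 <- render_lifespan_pair(7, 7, seed = 6, canvas = c(700, 1000))
  expect_identical(p7$truth$n_moving, 7)
})
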