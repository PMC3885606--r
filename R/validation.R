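# Desk-scale validation protocols: synthetic analogs of the published
# accuracy studies, each returning the measured error statistic together
# with the per-item details. The locomotion study is reproduced exactly
# (it was simulation-based in the original); the still-image studies use
# the simulator's ground-truth manifests in place of manual oracles.

derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2^30, n))
}

#' Velocity-accuracy validation
#'
#' Generates seeded 30-s, 7-fps, 640x480 videos of sinusoidal worms moving
#' straight at constant known speeds spanning 0.25-2 px/frame, runs the
#' tracker on each, and reports the mean absolute percent difference
#' between the estimated and true mean velocity per video.
#'
#' @param seed Integer seed.
#' @param n_videos Number of videos (one speed each, evenly spaced).
#' @param n_worms Worms per video.
#' @param n_frames Frames per video (210 = 30 s at 7 fps).
#' @return List: `mape` (percent), `per_video` data frame, `n`.
#' @export
validate_velocity <- function(seed = 1, n_videos = 11, n_worms = 6,
                              n_frames = 210) {
  speeds <- seq(0.25, 2, length.out = n_videos)
  seeds <- derive_seeds(seed, n_videos)
  p <- tracker_params(fps = 7, scale = 20)
  rows <- lapply(seq_len(n_videos), function(i) {
    cfg <- sim_video_config(rep(speeds[i], n_worms), seed = seeds[i],
                            frame_size = c(480, 640), fps = 7,
                            n_frames = n_frames)
    v <- render_worm_video(cfg)
    res <- track_video(v, p)
    tab <- res$summary$tracks
    tab <- tab[tab$included, , drop = FALSE]
    est <- mean(tab$speed_px_frame)
    data.frame(video = i, true_speed = speeds[i], est_speed = est,
               n_tracks = nrow(tab),
               pct_diff = 100 * abs(est - speeds[i]) / speeds[i])
  })
  per_video <- do.call(rbind, rows)
  list(mape = mean(per_video$pct_diff), per_video = per_video,
       n = n_videos)
}

#' Two-cohort track-recovery validation
#'
#' Renders the published validation video configuration (ten worms at
#' 1 px/frame plus ten at 0.25 px/frame, 7 fps) with non-crossing seeded
#' placement and counts the distinct recovered tracks faster than
#' 0.5 px/frame.
#'
#' @param seed Integer seed.
#' @return List: `n_fast_tracks`, `n_tracks`, `summary`.
#' @export
validate_cohort <- function(seed = 1) {
  cfg <- movie_s1_config(seed = derive_seeds(seed, 1))
  v <- render_worm_video(cfg)
  res <- track_video(v, tracker_params(fps = 7, scale = 20))
  tab <- res$summary$tracks
  list(n_fast_tracks = sum(tab$speed_px_frame > 0.5),
       n_tracks = nrow(tab), summary = res$summary)
}

#' Body-length accuracy validation
#'
#' Renders seeded plates totalling `n_worms` non-overlapping sinusoidal
#' worms of analytically known arc length (600-1500 px at 20 um/px, varied
#' curvature and orientation), measures them, and reports the mean absolute
#' percent error of the valid measurements against the manifest.
#'
#' @param seed Integer seed.
#' @param n_worms Total number of worms across plates.
#' @return List: `mape` (percent), `per_worm` data frame, `n` (valid
#'   measurements compared).
#' @export
validate_length <- function(seed = 1, n_worms = 46) {
  per_plate <- 8
  counts <- rep(per_plate, n_worms %/% per_plate)
  if (n_worms %% per_plate) counts <- c(counts, n_worms %% per_plate)
  seeds <- derive_seeds(seed, length(counts))
  lp <- length_params(min_area = 1000, max_area = 40000,
                      fatness_range = c(4, 16), min_bbox_side = 30)
  rows <- list()
  for (k in seq_along(counts)) {
    plate <- render_length_plate(counts[k], length_range = c(600, 1500),
                                 seed = seeds[k], canvas = c(2200, 2200),
                                 thickness = 9, scale = 20)
    m <- measure_worms(plate$image, lp)
    v <- m[m$valid, , drop = FALSE]
    tr <- plate$truth
    for (i in seq_len(nrow(v))) {
      j <- which.min((tr$center_r - v$centroid_r[i])^2 +
                       (tr$center_c - v$centroid_c[i])^2)
      rows[[length(rows) + 1L]] <- data.frame(
        plate = k, true_px = tr$arc_length_px[j], est_px = v$length_px[i],
        pct_err = 100 * abs(v$length_px[i] - tr$arc_length_px[j]) /
          tr$arc_length_px[j])
    }
  }
  per_worm <- do.call(rbind, rows)
  list(mape = mean(per_worm$pct_err), per_worm = per_worm,
       n = nrow(per_worm))
}

#' Egg-count accuracy validation
#'
#' Renders seeded egg plates (10-80 eggs, touching clusters, blob and
#' track-mark debris), counts each, and reports the mean absolute count
#' error.
#'
#' @param seed Integer seed.
#' @param n_plates Number of plates.
#' @return List: `mae` (eggs), `per_plate` data frame, `n`.
#' @export
validate_eggs <- function(seed = 1, n_plates = 42) {
  seeds <- derive_seeds(seed, n_plates + 1)
  setup <- with_seed(seeds[n_plates + 1], data.frame(
    n_eggs = sample(10:80, n_plates, replace = TRUE),
    debris = sample(5:15, n_plates, replace = TRUE)))
  rows <- lapply(seq_len(n_plates), function(k) {
    p <- render_egg_plate(setup$n_eggs[k], cluster_fraction = 0.3,
                          debris_count = setup$debris[k], seed = seeds[k])
    n <- tryCatch(count_eggs(p$image)$n_eggs, error = function(e) 0L)
    data.frame(plate = k, true = setup$n_eggs[k], counted = n,
               abs_err = abs(n - setup$n_eggs[k]))
  })
  per_plate <- do.call(rbind, rows)
  list(mae = mean(per_plate$abs_err), per_plate = per_plate, n = n_plates)
}

#' Moving-worm-count accuracy validation
#'
#' Renders seeded two-image time-lapse pairs spanning 0-100 movers with
#' additional stationary worms and dark debris on an assembled-well-sized
#' canvas, counts moving worms in each, and reports the mean absolute
#' count error.
#'
#' @param seed Integer seed.
#' @param movers Vector of true moving-worm counts (default 0, 4, ..., 100:
#'   26 wells).
#' @return List: `mae` (worms), `per_pair` data frame, `n`.
#' @export
validate_lifespan <- function(seed = 1, movers = seq(0, 100, by = 4)) {
  n <- length(movers)
  seeds <- derive_seeds(seed, n + 1)
  setup <- with_seed(seeds[n + 1], data.frame(
    stills = sample(5:20, n, replace = TRUE),
    debris = sample(3:8, n, replace = TRUE)))
  p <- lifespan_params()
  rows <- lapply(seq_len(n), function(k) {
    pair <- render_lifespan_pair(movers[k], setup$stills[k],
                                 debris_count = setup$debris[k],
                                 seed = seeds[k])
    r <- count_moving_worms(pair$img1, pair$img2, p)
    data.frame(pair = k, true = movers[k], counted = r$n_moving,
               abs_err = abs(r$n_moving - movers[k]))
  })
  per_pair <- do.call(rbind, rows)
  list(mae = mean(per_pair$abs_err), per_pair = per_pair, n = n)
}
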