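# Multi-worm video tracking and velocity statistics.

#' Parameters for multi-worm tracking
#'
#' @param min_worm_area,max_worm_area Region area limits, px.
#' @param min_eccentricity Elongation floor a region must exceed to be a
#'   worm (rejects round debris of worm-like area).
#' @param max_step Association gate: largest centroid displacement per
#'   frame, px.
#' @param max_area_change Largest relative area change tolerated when
#'   extending a track.
#' @param collision_area_factor A region larger than this multiple of a
#'   track's running median area ends the track as a collision (two worms
#'   merged into one blob).
#' @param min_track_frames Tracks shorter than this many frames are
#'   discarded (default 14 = 2 s at 7 fps).
#' @param stationary_box Side of the bounding box, px, below which a whole
#'   trail is deemed a non-moving object and excluded from velocity
#'   statistics.
#' @param path_stride Frame stride at which the smoothed path is sampled
#'   when summing step distances (default 14, about two seconds of video).
#'   Per-frame sampling makes residual centroid jitter accumulate into a
#'   spurious random-walk length for slow worms; chord sampling at about
#'   1 s suppresses it while leaving genuine path curvature (radii well
#'   above one stride length) intact.
#' @param fps Frames per second of the video.
#' @param scale Micrometers per pixel.
#' @param window,offset_fraction Adaptive-threshold settings.
#' @return A `tracker_params` list.
#' @export
tracker_params <- function(min_worm_area = 40, max_worm_area = 2000,
                           min_eccentricity = 0.7, max_step = 10,
                           max_area_change = 0.6,
                           collision_area_factor = 1.6,
                           min_track_frames = 14, stationary_box = 5,
                           path_stride = 14L, fps = 7, scale = 20,
                           window = NULL, offset_fraction = 0.15) {
  stopifnot(max_step > 0, min_track_frames >= 2, fps > 0, scale > 0,
            min_worm_area < max_worm_area, path_stride >= 1)
  structure(list(min_worm_area = min_worm_area,
                 max_worm_area = max_worm_area,
                 min_eccentricity = min_eccentricity,
                 max_step = max_step, max_area_change = max_area_change,
                 collision_area_factor = collision_area_factor,
                 min_track_frames = min_track_frames,
                 stationary_box = stationary_box,
                 path_stride = as.integer(path_stride),
                 fps = fps, scale = scale,
                 window = window, offset_fraction = offset_fraction),
            class = "tracker_params")
}

#' Detect worm-shaped objects in one video frame
#'
#' Adaptive thresholding, connected-component labeling, then a morphology
#' filter keeping regions whose area lies within the worm limits and whose
#' eccentricity exceeds the elongation floor.
#'
#' @param frame A `gray_image` or intensity matrix.
#' @param p A [tracker_params()].
#' @return A `worm_regions` data frame (possibly zero rows).
#' @export
detect_frame_objects <- function(frame, p = tracker_params()) {
  bin <- adaptive_threshold(frame, window = p$window,
                            offset_fraction = p$offset_fraction)
  regs <- label_regions(bin, 8)
  regs[regs$area >= p$min_worm_area & regs$area <= p$max_worm_area &
         regs$eccentricity >= p$min_eccentricity, , drop = FALSE]
}

#' Build worm tracks from per-frame detections
#'
#' Greedy nearest-centroid association (ties broken by smaller area
#' difference) gated by `max_step` and by relative area change. A track
#' ends with reason `"collision"` when two active tracks claim the same
#' region or the claimed region exceeds `collision_area_factor` times the
#' track's running median area (a merge); `"boundary"` when its region
#' touches the frame edge; `"lost"` when no region matches; `"video_end"`
#' otherwise. Tracks shorter than `min_track_frames` are dropped.
#'
#' @param frame_regions List (one element per frame) of `worm_regions`.
#' @param p A [tracker_params()].
#' @param frame_dim `(height, width)` of the frames, required for boundary
#'   detection; taken from the labels attribute when available.
#' @return List of class `track_set`; each element is a `worm_track` with
#'   `id`, `frames`, `centroids`, `areas`, `end_reason`.
#' @export
build_tracks <- function(frame_regions, p = tracker_params(),
                         frame_dim = NULL) {
  if (length(frame_regions) < 2) stop("need at least 2 frames")
  if (is.null(frame_dim)) {
    for (fr in frame_regions) {
      lbl <- attr(fr, "labels")
      if (!is.null(lbl)) { frame_dim <- dim(lbl); break }
    }
    if (is.null(frame_dim)) stop("`frame_dim` required")
  }

  active <- list()   # each: list(id, frames, rows of centroid, areas)
  done <- list()
  next_id <- 1L

  finish <- function(tr, reason) {
    tr$end_reason <- reason
    done[[length(done) + 1L]] <<- tr
  }
  touches_edge <- function(reg, i) {
    reg$min_row[i] <= 1 || reg$min_col[i] <= 1 ||
      reg$max_row[i] >= frame_dim[1] || reg$max_col[i] >= frame_dim[2]
  }

  for (f in seq_along(frame_regions)) {
    regs <- frame_regions[[f]]
    m <- if (is.null(regs)) 0L else nrow(regs)
    claimed <- integer(0)

    if (length(active) && m) {
      # gated nearest region for every active track
      claims <- vapply(active, function(tr) {
        last <- tr$centroids[nrow(tr$centroids), ]
        med_area <- stats::median(tr$areas)
        d <- sqrt((regs$centroid_r - last[1])^2 +
                    (regs$centroid_c - last[2])^2)
        ok <- d <= p$max_step &
          abs(regs$area - med_area) / med_area <= p$max_area_change
        big <- d <= p$max_step &
          regs$area > p$collision_area_factor * med_area
        if (any(big)) return(-which(big)[1])    # merge-collision marker
        if (!any(ok)) return(0L)
        cand <- which(ok)
        cand[order(d[cand], abs(regs$area[cand] - med_area))][1]
      }, numeric(1))

      keep <- logical(length(active))
      pos_claims <- claims[claims > 0]
      dup <- unique(pos_claims[duplicated(pos_claims)])
      for (k in seq_along(active)) {
        cl <- claims[k]
        if (cl < 0) {                     # merged blob: collision
          finish(active[[k]], "collision")
          claimed <- c(claimed, -cl)
        } else if (cl == 0) {
          finish(active[[k]], "lost")
        } else if (cl %in% dup) {         # contested region: collision
          finish(active[[k]], "collision")
          claimed <- c(claimed, cl)
        } else {
          tr <- active[[k]]
          tr$frames <- c(tr$frames, f)
          tr$centroids <- rbind(tr$centroids,
                                c(regs$centroid_r[cl], regs$centroid_c[cl]))
          tr$areas <- c(tr$areas, regs$area[cl])
          claimed <- c(claimed, cl)
          if (touches_edge(regs, cl)) {
            finish(tr, "boundary")
          } else {
            active[[k]] <- tr
            keep[k] <- TRUE
          }
        }
      }
      active <- active[keep]
    } else if (length(active)) {
      for (tr in active) finish(tr, "lost")
      active <- list()
    }

    if (m) {
      for (i in setdiff(seq_len(m), claimed)) {
        if (touches_edge(regs, i)) next   # don't seed tracks on the border
        active[[length(active) + 1L]] <- list(
          id = next_id, frames = f,
          centroids = matrix(c(regs$centroid_r[i], regs$centroid_c[i]),
                             1, 2, dimnames = list(NULL, c("row", "col"))),
          areas = regs$area[i])
        next_id <- next_id + 1L
      }
    }
  }
  for (tr in active) finish(tr, "video_end")

  done <- Filter(function(tr) length(tr$frames) >= p$min_track_frames, done)
  done <- lapply(done, function(tr) structure(tr, class = "worm_track"))
  structure(done, class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d track(s)\n", length(x)))
  invisible(x)
}

#' @export
print.worm_track <- function(x, ...) {
  cat(sprintf("<worm_track> id %d, frames %d..%d (%d pts), end: %s\n",
              x$id, min(x$frames), max(x$frames), length(x$frames),
              x$end_reason))
  invisible(x)
}

# Least-squares cubic fit over sliding windows, cross-faded with
# triangular weights where windows overlap. Same point count in and out.
piecewise_poly_smooth <- function(pts, window = 7L, overlap = 3L) {
  n <- nrow(pts)
  if (n < 3L) return(pts)
  window <- min(window, n)
  step <- max(window - overlap, 1L)
  starts <- unique(c(seq(1L, max(n - window + 1L, 1L), by = step),
                     n - window + 1L))
  acc <- matrix(0, n, 2)
  wsum <- numeric(n)
  for (s in starts) {
    id <- s:(s + window - 1L)
    t <- seq_along(id) - (window + 1) / 2
    deg <- min(3L, window - 1L)
    X <- outer(t, 0:deg, `^`)
    fit <- X %*% qr.solve(X, pts[id, , drop = FALSE])
    wgt <- pmin(seq_len(window), rev(seq_len(window)))
    acc[id, ] <- acc[id, ] + fit * wgt
    wsum[id] <- wsum[id] + wgt
  }
  out <- acc / wsum
  dimnames(out) <- dimnames(pts)
  out
}

#' Smooth a raw centroid trail
#'
#' Piecewise cubic least-squares (Bezier-style) fit over sliding windows of
#' 7 samples with 3-sample overlap, blended where windows meet. Removes the
#' frame-to-frame positional flicker of detection centroids without
#' distorting genuine path curvature. Inputs with fewer than 3 points are
#' returned unchanged.
#'
#' @param raw_centroids n x 2 matrix of `(row, col)` positions.
#' @param window,overlap Window length and overlap in samples.
#' @return n x 2 matrix of smoothed positions.
#' @export
smooth_track <- function(raw_centroids, window = 7L, overlap = 3L) {
  pts <- as.matrix(raw_centroids)
  piecewise_poly_smooth(pts, window = window, overlap = overlap)
}

#' Mean velocity of one track
#'
#' Path length is the sum of Euclidean steps along the smoothed trail
#' converted to micrometers; duration is the spanned frame count over the
#' frame rate. Tracks whose whole smoothed trail fits inside a
#' `stationary_box`-sided bounding box are marked excluded (a worm
#' undulating in place has no meaningful translocation speed).
#'
#' @param track A `worm_track`.
#' @param p A [tracker_params()].
#' @return List: `velocity_um_s`, `speed_px_frame`, `path_length_um`,
#'   `duration_s`, `included` (FALSE for stationary trails).
#' @export
track_velocity <- function(track, p = tracker_params()) {
  nf <- length(track$frames)
  span <- track$frames[nf] - track$frames[1]
  if (span <= 0) stop("track spans zero frames; velocity undefined")
  sm <- smooth_track(track$centroids)
  samp <- unique(c(seq(1L, nrow(sm), by = p$path_stride), nrow(sm)))
  len_px <- polyline_length(sm[samp, , drop = FALSE])
  box <- c(diff(range(sm[, 1])), diff(range(sm[, 2])))
  duration <- span / p$fps
  list(velocity_um_s = len_px * p$scale / duration,
       speed_px_frame = len_px / span,
       path_length_um = len_px * p$scale,
       duration_s = duration,
       included = max(box) >= p$stationary_box)
}

#' Population velocity summary
#'
#' @param tracks A `track_set`.
#' @param p A [tracker_params()].
#' @param breaks Histogram bin specification (passed to [hist()]).
#' @return Object of class `velocity_summary`: per-track table (id,
#'   velocity, duration, end reason, included flag), `n_tracks` (included),
#'   `n_excluded`, `mean`, `sd`, histogram counts and an empirical
#'   cumulative distribution table. With zero included tracks the summary
#'   is flagged `empty = TRUE`.
#' @export
summarize_velocities <- function(tracks, p = tracker_params(),
                                 breaks = "Sturges") {
  rows <- lapply(tracks, function(tr) {
    v <- track_velocity(tr, p)
    data.frame(id = tr$id, velocity_um_s = v$velocity_um_s,
               speed_px_frame = v$speed_px_frame,
               duration_s = v$duration_s, end_reason = tr$end_reason,
               included = v$included)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), velocity_um_s = numeric(),
               speed_px_frame = numeric(), duration_s = numeric(),
               end_reason = character(), included = logical())
  inc <- tab[tab$included, , drop = FALSE]
  empty <- nrow(inc) == 0
  hist_obj <- if (!empty)
    graphics::hist(inc$velocity_um_s, breaks = breaks, plot = FALSE) else NULL
  ecdf_tab <- if (!empty) {
    v <- sort(inc$velocity_um_s)
    data.frame(velocity_um_s = v,
               cumulative_probability = seq_along(v) / length(v))
  } else data.frame(velocity_um_s = numeric(),
                    cumulative_probability = numeric())
  structure(list(tracks = tab, n_tracks = nrow(inc),
                 n_excluded = nrow(tab) - nrow(inc),
                 mean = if (empty) NA_real_ else mean(inc$velocity_um_s),
                 sd = if (empty) NA_real_ else stats::sd(inc$velocity_um_s),
                 histogram = hist_obj, cumulative = ecdf_tab,
                 empty = empty),
            class = "velocity_summary")
}

#' @export
print.velocity_summary <- function(x, ...) {
  if (x$empty) {
    cat("<velocity_summary> no included tracks\n")
  } else {
    cat(sprintf(
      "<velocity_summary> %d track(s) (+%d excluded), mean %.1f um/s, sd %.1f\n",
      x$n_tracks, x$n_excluded, x$mean, x$sd))
  }
  invisible(x)
}

#' @export
plot.velocity_summary <- function(x, ...) {
  if (x$empty) stop("nothing to plot: no included tracks")
  graphics::plot(x$histogram, xlab = "velocity (um/s)",
                 main = "worm velocity distribution", ...)
  invisible(x)
}

#' Analyze a whole video
#'
#' Runs detection on every frame, builds and smooths tracks, and computes
#' the velocity summary.
#'
#' @param frames A `sim_video`, a list of `gray_image`/matrices, or a
#'   directory of numbered PNG frames.
#' @param p A [tracker_params()].
#' @return List of class `locomotion_result`: `tracks` (a `track_set`) and
#'   `summary` (a `velocity_summary`).
#' @export
track_video <- function(frames, p = tracker_params()) {
  if (inherits(frames, "sim_video")) frames <- frames$frames
  if (is.character(frames) && length(frames) == 1L && dir.exists(frames)) {
    paths <- sort(list.files(frames, pattern = "\\.png$", full.names = TRUE))
    if (!length(paths)) stop("no PNG frames found in ", frames)
    frames <- lapply(paths, function(f) read_gray_image(f, scale = p$scale))
  }
  frame_dim <- dim(as_pixels(frames[[1]]))
  frame_regions <- lapply(frames, detect_frame_objects, p = p)
  tracks <- build_tracks(frame_regions, p, frame_dim = frame_dim)
  structure(list(tracks = tracks, summary = summarize_velocities(tracks, p)),
            class = "locomotion_result")
}

#' @export
print.locomotion_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
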