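# Synthetic plate/video generator with ground-truth manifests.
#
# Virtual worms are constant-thickness bands swept along a sinusoidal
# midline. The lateral offset is A*sin(2*pi*u/lambda + phi) over a centered
# support u in [-E/2, E/2]; when the support holds an integer number of
# waves the curve centroid is exactly the worm's nominal position for every
# phase, so a moving virtual worm's true centroid advances at exactly its
# configured speed and the phase modulation only changes its posture.

# Evaluate RNG-dependent code under `seed`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Arc length of the sinusoidal midline with support E, amplitude A,
# wavelength lambda, phase phi, by adaptive quadrature.
sine_arc_length <- function(E, amplitude, wavelength, phase = 0) {
  if (amplitude == 0) return(E)
  k <- 2 * pi / wavelength
  f <- function(u) sqrt(1 + (amplitude * k * cos(k * u + phase))^2)
  stats::integrate(f, -E / 2, E / 2, rel.tol = 1e-9,
                   subdivisions = 400L)$value
}

# Solve for the support E giving a target arc length (waves = E / lambda).
solve_support <- function(arc_length, amplitude, waves, phase = 0) {
  if (amplitude == 0) return(arc_length)
  f <- function(E) sine_arc_length(E, amplitude, E / waves, phase) - arc_length
  lo <- arc_length * 0.05; hi <- arc_length
  if (f(lo) > 0)   # arc length exceeds the target even at the smallest support
    stop("no support solves this arc length; amplitude too large for length")
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

disc_offsets <- function(thickness) {
  radius <- max(thickness, 1) / 2
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

# Continuous midline points of a worm at a given center/phase.
worm_midline <- function(center, heading, E, amplitude, wavelength, phase,
                         step = 0.35) {
  u <- seq(-E / 2, E / 2, by = step)
  if (u[length(u)] < E / 2) u <- c(u, E / 2)
  w <- if (amplitude == 0) rep(0, length(u))
       else amplitude * sin(2 * pi * u / wavelength + phase)
  ch <- cos(heading); sh <- sin(heading)
  cbind(row = center[1] + u * sh + w * ch,
        col = center[2] + u * ch - w * sh)
}

# Linear pixel indices of a band of `thickness` swept along midline points.
band_indices <- function(pts, thickness, dims) {
  off <- disc_offsets(thickness)
  r <- round(rep(pts[, 1], each = nrow(off)) + off[, 1])
  c <- round(rep(pts[, 2], each = nrow(off)) + off[, 2])
  ok <- r >= 1 & r <= dims[1] & c >= 1 & c <= dims[2]
  unique((c[ok] - 1L) * dims[1] + r[ok])
}

# Stamp a worm body (midline points dilated to `thickness`) into a canvas.
stamp_band <- function(canvas, pts, thickness, level) {
  idx <- band_indices(pts, thickness, dim(canvas))
  canvas[idx] <- pmin(canvas[idx], level)
  canvas
}

add_noise <- function(canvas, noise_sd) {
  if (noise_sd > 0)
    canvas <- canvas + stats::rnorm(length(canvas), 0, noise_sd)
  matrix(pmin(pmax(round(canvas), 0), 255), nrow(canvas), ncol(canvas))
}

#' Virtual worm specification
#'
#' @param id Integer id.
#' @param start `(row, col)` start position of the body center, pixels.
#' @param heading Direction of motion (and body axis), radians;
#'   0 points along increasing column.
#' @param speed Pixels per frame (>= 0).
#' @param body_length Arc length of the midline, pixels.
#' @param amplitude Undulation amplitude, pixels.
#' @param waves Number of full sine waves along the body. Integer values
#'   keep the body centroid exactly on the nominal position for all phases.
#' @param phase,phase_rate Initial undulation phase (rad) and its advance
#'   per frame (rad/frame).
#' @param thickness Body thickness, pixels (>= 1).
#' @return A `sim_worm` list; the sinusoid support `u_extent` and
#'   `wavelength` are derived from `body_length`, `amplitude` and `waves`.
#' @export
sim_worm <- function(id = 1L, start = c(100, 100), heading = 0, speed = 1,
                     body_length = 40, amplitude = 4, waves = 1,
                     phase = 0, phase_rate = 0.4, thickness = 3) {
  stopifnot(speed >= 0, body_length > 0, amplitude >= 0, thickness >= 1,
            waves > 0)
  E <- solve_support(body_length, amplitude, waves, phase = 0)
  structure(list(id = as.integer(id), start = as.numeric(start),
                 heading = heading, speed = speed, body_length = body_length,
                 amplitude = amplitude, waves = waves,
                 wavelength = E / waves, u_extent = E,
                 phase = phase, phase_rate = phase_rate,
                 thickness = thickness),
            class = "sim_worm")
}

#' Simulation video configuration
#'
#' @param worms List of [sim_worm()] objects.
#' @param frame_size `(height, width)` in pixels.
#' @param fps Frames per second (> 0).
#' @param n_frames Number of frames (>= 2).
#' @param background_level,worm_level Background and body intensities in
#'   `[0, 255]` (bright agar, dark worms).
#' @param noise_sd Gaussian intensity noise per pixel per frame.
#' @param scale Micrometers per pixel.
#' @param seed Integer RNG seed for rendering noise.
#' @return A `sim_config` list.
#' @export
sim_config <- function(worms, frame_size = c(480, 640), fps = 7,
                       n_frames = 210, background_level = 220,
                       worm_level = 30, noise_sd = 6, scale = 20,
                       seed = 1) {
  stopifnot(fps > 0, n_frames >= 2,
            background_level >= 0, background_level <= 255,
            worm_level >= 0, worm_level <= 255)
  structure(list(worms = worms, frame_size = as.integer(frame_size),
                 fps = fps, n_frames = as.integer(n_frames),
                 background_level = background_level,
                 worm_level = worm_level, noise_sd = noise_sd,
                 scale = scale, seed = as.integer(seed)),
            class = "sim_config")
}

worm_radius <- function(w) w$u_extent / 2 + w$amplitude + w$thickness

#' Render a worm simulation video
#'
#' Draws every configured worm in every frame: the body center advances by
#' `speed` pixels per frame along `heading`, and the undulation phase
#' advances by `phase_rate`, modulating the sinusoidal posture in place.
#' High-contrast frames (dark worms on bright agar) with per-frame Gaussian
#' noise are produced, together with a ground-truth manifest holding each
#' worm's true speed and analytic centroid trajectory.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory: frames are written as numbered PNGs
#'   plus `manifest.json`.
#' @return A list of class `sim_video`: `frames` (list of integer intensity
#'   matrices), `truth` (data frame: id, speed_px_frame, speed_um_s,
#'   heading), `trajectories` (per-worm true centroid matrices), and the
#'   config.
#' @export
render_worm_video <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  h <- cfg$frame_size[1]; w <- cfg$frame_size[2]
  for (wm in cfg$worms) {
    rad <- worm_radius(wm)
    if (wm$start[1] - rad < 1 || wm$start[1] + rad > h ||
        wm$start[2] - rad < 1 || wm$start[2] + rad > w)
      stop(sprintf("worm %d starts outside the frame", wm$id))
  }
  with_seed(cfg$seed, {
    frames <- vector("list", cfg$n_frames)
    traj <- lapply(cfg$worms, function(wm)
      matrix(NA_real_, cfg$n_frames, 2, dimnames = list(NULL, c("row", "col"))))
    for (t in seq_len(cfg$n_frames)) {
      canvas <- matrix(cfg$background_level, h, w)
      for (i in seq_along(cfg$worms)) {
        wm <- cfg$worms[[i]]
        tt <- t - 1L
        center <- wm$start +
          tt * wm$speed * c(sin(wm$heading), cos(wm$heading))
        traj[[i]][t, ] <- center
        pts <- worm_midline(center, wm$heading, wm$u_extent, wm$amplitude,
                            wm$wavelength, wm$phase + tt * wm$phase_rate)
        canvas <- stamp_band(canvas, pts, wm$thickness, cfg$worm_level)
      }
      frames[[t]] <- add_noise(canvas, cfg$noise_sd)
    }
    truth <- data.frame(
      id = vapply(cfg$worms, `[[`, integer(1), "id"),
      speed_px_frame = vapply(cfg$worms, `[[`, numeric(1), "speed"),
      speed_um_s = vapply(cfg$worms, function(x)
        x$speed * cfg$fps * cfg$scale, numeric(1)),
      heading = vapply(cfg$worms, `[[`, numeric(1), "heading"))
    out <- structure(list(frames = frames, truth = truth,
                          trajectories = traj, config = cfg),
                     class = "sim_video")
    if (!is.null(out_dir)) write_sim_video(out, out_dir)
    out
  })
}

#' @export
print.sim_video <- function(x, ...) {
  cat(sprintf("<sim_video> %d frames %dx%d px, %d worm(s), %g fps\n",
              length(x$frames), x$config$frame_size[1],
              x$config$frame_size[2], nrow(x$truth), x$config$fps))
  invisible(x)
}

write_sim_video <- function(video, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf(file.path(out_dir, "frame_%04d.png"),
                   seq_along(video$frames))
  for (i in seq_along(video$frames))
    png::writePNG(video$frames[[i]] / 255, target = paths[i])
  manifest <- list(kind = "worm_video", fps = video$config$fps,
                   scale_um_px = video$config$scale,
                   n_frames = length(video$frames),
                   worms = video$truth, frames = basename(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# Deterministic rejection placement: sample start positions and headings so
# that every worm's full trajectory stays inside the frame margin and all
# pairwise centroid clearances hold for the whole video. Keeps track
# identity (not collision handling) as the quantity a validation measures.
place_video_worms <- function(speeds, frame_size, n_frames,
                              body_length = 40, amplitude = 4, waves = 1,
                              thickness = 3, clearance = 8,
                              max_tries = 2000L) {
  proto <- sim_worm(body_length = body_length, amplitude = amplitude,
                    waves = waves, thickness = thickness)
  rad <- worm_radius(proto)
  h <- frame_size[1]; w <- frame_size[2]
  tsamp <- unique(c(seq(0, n_frames - 1, by = 3), n_frames - 1))
  worms <- list()
  starts <- list(); dirs <- list()
  for (i in seq_along(speeds)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      heading <- stats::runif(1, 0, 2 * pi)
      d <- c(sin(heading), cos(heading))
      start <- c(stats::runif(1, rad + 2, h - rad - 1),
                 stats::runif(1, rad + 2, w - rad - 1))
      endp <- start + speeds[i] * (n_frames - 1) * d
      if (endp[1] - rad < 2 || endp[1] + rad > h - 1 ||
          endp[2] - rad < 2 || endp[2] + rad > w - 1) next
      ok <- TRUE
      for (j in seq_along(worms)) {
        pj <- outer(tsamp * speeds[j], dirs[[j]]) +
          matrix(starts[[j]], length(tsamp), 2, byrow = TRUE)
        pi_ <- outer(tsamp * speeds[i], d) +
          matrix(start, length(tsamp), 2, byrow = TRUE)
        if (min(sqrt(rowSums((pi_ - pj)^2))) < 2 * rad + clearance) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      worms[[i]] <- sim_worm(id = i, start = start, heading = heading,
                             speed = speeds[i], body_length = body_length,
                             amplitude = amplitude, waves = waves,
                             phase = stats::runif(1, 0, 2 * pi),
                             phase_rate = stats::runif(1, 0.3, 0.5),
                             thickness = thickness)
      starts[[i]] <- start; dirs[[i]] <- d
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place worms without trajectory overlap; ",
           "reduce worm count, speed or video length")
  }
  worms
}

#' Build a collision-free simulation video configuration
#'
#' Convenience wrapper: places one worm per requested speed at a random
#' position and heading such that no two trajectories ever come close and no
#' worm leaves the frame, then returns the [sim_config()].
#'
#' @param speeds Numeric vector, one entry per worm, px/frame.
#' @param seed Integer seed controlling placement and rendering noise.
#' @param frame_size,fps,n_frames,scale See [sim_config()].
#' @param ... Worm body parameters passed to the placement routine
#'   (`body_length`, `amplitude`, `waves`, `thickness`).
#' @return A `sim_config`.
#' @export
sim_video_config <- function(speeds, seed = 1, frame_size = c(480, 640),
                             fps = 7, n_frames = 210, scale = 20, ...) {
  with_seed(seed, {
    worms <- place_video_worms(speeds, frame_size, n_frames, ...)
    sim_config(worms, frame_size = frame_size, fps = fps,
               n_frames = n_frames, scale = scale, seed = seed + 1L)
  })
}

#' Movie-S1-style two-cohort video configuration
#'
#' The published validation video: 7 frames/s, ten virtual worms moving at
#' 1 px/frame and ten at 0.25 px/frame, straight in random directions.
#'
#' @param seed Integer seed.
#' @param n_frames Number of frames (default 210 = 30 s at 7 fps).
#' @return A `sim_config` with 20 worms in two speed cohorts.
#' @export
movie_s1_config <- function(seed = 1, n_frames = 210) {
  sim_video_config(c(rep(1, 10), rep(0.25, 10)), seed = seed,
                   frame_size = c(480, 640), fps = 7, n_frames = n_frames)
}

#' Render a still plate of worms with known arc lengths
#'
#' Each worm is a constant-thickness band along a sinusoidal midline whose
#' true arc length is computed by numeric quadrature of the generating
#' curve and recorded in the manifest. Worms are placed by seeded rejection
#' sampling so that no two bodies overlap.
#'
#' @param n_worms Number of worms (0 gives a blank plate).
#' @param length_range Arc-length range in px; each worm's target length is
#'   drawn uniformly from it.
#' @param seed Integer seed.
#' @param canvas `(height, width)` px.
#' @param thickness Body thickness px.
#' @param waves_choices Candidate wave counts (curvature variety).
#' @param rel_amplitude_range Amplitude as a fraction of the sinusoid
#'   support; `c(0, 0)` renders straight worms.
#' @param background_level,worm_level,noise_sd,scale Rendering parameters.
#' @return List of class `sim_plate`: `image` (a `gray_image`) and `truth`
#'   (data frame: id, arc_length_px, arc_length_um, center, heading).
#' @export
render_length_plate <- function(n_worms, length_range = c(600, 1500),
                                seed = 1, canvas = c(2048, 2048),
                                thickness = 9,
                                waves_choices = c(1, 1.5, 2),
                                rel_amplitude_range = c(0.04, 0.10),
                                background_level = 220, worm_level = 30,
                                noise_sd = 6, scale = 20) {
  stopifnot(n_worms >= 0)
  with_seed(seed, {
    img <- matrix(background_level, canvas[1], canvas[2])
    occupied <- matrix(FALSE, canvas[1], canvas[2])
    truth <- data.frame(id = integer(), arc_length_px = numeric(),
                        arc_length_um = numeric(), center_r = numeric(),
                        center_c = numeric(), heading = numeric())
    margin <- thickness + 2
    for (i in seq_len(n_worms)) {
      L <- stats::runif(1, length_range[1], length_range[2])
      waves <- sample(waves_choices, 1)
      a_rel <- stats::runif(1, rel_amplitude_range[1], rel_amplitude_range[2])
      # amplitude proportional to support: arc scales linearly with E
      c_per_unit <- sine_arc_length(1, a_rel, 1 / waves)
      E <- L / c_per_unit
      A <- a_rel * E
      placed <- FALSE
      for (try in seq_len(600L)) {
        heading <- stats::runif(1, 0, 2 * pi)
        center <- c(stats::runif(1, margin, canvas[1] - margin),
                    stats::runif(1, margin, canvas[2] - margin))
        phase <- stats::runif(1, 0, 2 * pi)
        pts <- worm_midline(center, heading, E, A, E / waves, phase)
        if (min(pts[, 1]) < margin || max(pts[, 1]) > canvas[1] - margin ||
            min(pts[, 2]) < margin || max(pts[, 2]) > canvas[2] - margin)
          next
        # inflated band enforces a clearance gap between bodies
        probe <- band_indices(pts, thickness + 6, canvas)
        if (any(occupied[probe])) next
        body <- band_indices(pts, thickness, canvas)
        arc <- sine_arc_length(E, A, E / waves, phase)
        img[body] <- worm_level
        occupied[probe] <- TRUE
        truth <- rbind(truth, data.frame(
          id = i, arc_length_px = arc, arc_length_um = arc * scale,
          center_r = center[1], center_c = center[2], heading = heading))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place worm ", i, " without overlap at this density")
    }
    image <- gray_image(add_noise(img, noise_sd), scale = scale)
    structure(list(image = image, truth = truth,
                   params = list(kind = "length_plate", seed = seed,
                                 thickness = thickness, scale = scale)),
              class = "sim_plate")
  })
}

draw_ellipse <- function(canvas, center, a, b, theta, level) {
  rr <- ceiling(max(a, b))
  r0 <- max(1, round(center[1]) - rr); r1 <- min(nrow(canvas), round(center[1]) + rr)
  c0 <- max(1, round(center[2]) - rr); c1 <- min(ncol(canvas), round(center[2]) + rr)
  if (r0 > r1 || c0 > c1) return(canvas)
  g <- expand.grid(r = r0:r1, c = c0:c1)
  dr <- g$r - center[1]; dc <- g$c - center[2]
  xr <- dc * cos(theta) + dr * sin(theta)
  yr <- -dc * sin(theta) + dr * cos(theta)
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  canvas[cbind(g$r[inside], g$c[inside])] <-
    pmin(canvas[cbind(g$r[inside], g$c[inside])], level)
  canvas
}

#' Render a still egg plate with clusters and debris
#'
#' Eggs are dark ellipses (major:minor about 2:1.3). A `cluster_fraction`
#' share of eggs is placed touching a neighbor in pairs or triples. Debris
#' comprises irregular dark blobs and thin curvilinear track-like marks,
#' none of which belongs in the manifest egg count.
#'
#' @param n_eggs True number of eggs.
#' @param cluster_fraction Fraction of eggs placed in touching groups.
#' @param debris_count Number of debris objects (half blobs, half tracks).
#' @param seed Integer seed.
#' @param canvas `(height, width)` px.
#' @param egg_axes Mean ellipse semi-axes `(a, b)` px; per-egg jitter of
#'   about 12 percent is applied.
#' @param egg_intensity_range Egg gray-value range (eggs vary in optical
#'   density; faint eggs are only separable from background in a subset of
#'   threshold levels).
#' @param background_level,noise_sd,scale Rendering parameters.
#' @return List of class `sim_plate`: `image`, `truth` (with `n_eggs` and
#'   per-egg centers/areas), and parameters.
#' @export
render_egg_plate <- function(n_eggs, cluster_fraction = 0, debris_count = 0,
                             seed = 1, canvas = c(480, 640),
                             egg_axes = c(5, 3.25),
                             egg_intensity_range = c(60, 160),
                             background_level = 200, noise_sd = 5,
                             scale = 5) {
  stopifnot(n_eggs >= 0, cluster_fraction >= 0, cluster_fraction <= 1)
  with_seed(seed, {
    img <- matrix(background_level, canvas[1], canvas[2])
    margin <- 4 * egg_axes[1]
    centers <- matrix(numeric(0), 0, 2)
    eggs <- data.frame(id = integer(), center_r = numeric(),
                       center_c = numeric(), a = numeric(), b = numeric(),
                       intensity = numeric(), clustered = logical())

    n_clustered <- round(n_eggs * cluster_fraction)
    # split the clustered share into touching groups of 2-3
    group_sizes <- integer(0)
    left <- n_clustered
    while (left >= 2) {
      gs <- if (left >= 3 && stats::runif(1) < 0.4) 3L else 2L
      group_sizes <- c(group_sizes, gs); left <- left - gs
    }
    n_single <- n_eggs - sum(group_sizes)

    place_free <- function(min_sep) {
      for (try in seq_len(600L)) {
        p <- c(stats::runif(1, margin, canvas[1] - margin),
               stats::runif(1, margin, canvas[2] - margin))
        if (nrow(centers) == 0 ||
            min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)) >=
            min_sep) return(p)
      }
      stop("egg plate too crowded to place all objects")
    }
    draw_egg <- function(p, clustered) {
      a <- egg_axes[1] * stats::runif(1, 0.88, 1.12)
      b <- egg_axes[2] * stats::runif(1, 0.88, 1.12)
      th <- stats::runif(1, 0, pi)
      lev <- stats::runif(1, egg_intensity_range[1], egg_intensity_range[2])
      img <<- draw_ellipse(img, p, a, b, th, lev)
      centers <<- rbind(centers, p)
      eggs <<- rbind(eggs, data.frame(
        id = nrow(eggs) + 1L, center_r = p[1], center_c = p[2],
        a = a, b = b, intensity = lev, clustered = clustered))
      list(p = p, a = a, b = b, th = th)
    }

    for (g in group_sizes) {
      anchor <- draw_egg(place_free(5 * egg_axes[1]), TRUE)
      prev <- anchor
      for (k in seq_len(g - 1L)) {
        dir <- stats::runif(1, 0, 2 * pi)
        d <- 0.85 * (prev$a + egg_axes[1] * 0.9)
        p <- prev$p + d * c(sin(dir), cos(dir))
        p[1] <- min(max(p[1], margin), canvas[1] - margin)
        p[2] <- min(max(p[2], margin), canvas[2] - margin)
        prev <- draw_egg(p, TRUE)
      }
    }
    for (k in seq_len(n_single)) draw_egg(place_free(5 * egg_axes[1]), FALSE)

    # debris: irregular blobs and thin worm-track-like marks
    n_blob <- floor(debris_count / 2); n_track <- debris_count - n_blob
    for (k in seq_len(n_blob)) {
      p <- place_free(6 * egg_axes[1])
      lev <- stats::runif(1, 40, 90)
      for (s in seq_len(sample(3:6, 1))) {
        q <- p + stats::runif(2, -6, 6)
        img <- draw_ellipse(img, q, stats::runif(1, 2.5, 6),
                            stats::runif(1, 2.5, 6), 0, lev)
      }
      centers <- rbind(centers, p)
    }
    for (k in seq_len(n_track)) {
      p <- place_free(6 * egg_axes[1])
      heading <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 60, 180)
      amp <- stats::runif(1, 3, 10)
      pts <- worm_midline(p, heading, min(len, min(canvas) - 2 * margin),
                          amp, len / stats::runif(1, 1, 2),
                          stats::runif(1, 0, 2 * pi))
      img <- stamp_band(img, pts, stats::runif(1, 1, 2),
                        stats::runif(1, 90, 150))
      centers <- rbind(centers, p)
    }

    image <- gray_image(add_noise(img, noise_sd), scale = scale)
    structure(list(image = image,
                   truth = list(n_eggs = n_eggs, eggs = eggs,
                                n_debris = debris_count),
                   params = list(kind = "egg_plate", seed = seed,
                                 cluster_fraction = cluster_fraction,
                                 scale = scale)),
              class = "sim_plate")
  })
}

#' Render a two-image time-lapse pair with known moving-worm count
#'
#' Emulates the lifespan-assay acquisition: two images of the same plate a
#' couple of minutes apart. Moving worms are displaced by `displacement`
#' pixels along their heading and change undulation phase between the two
#' images; stationary worms and debris are identical in both (modulo
#' independent sensor noise).
#'
#' @param n_moving,n_still Worm counts.
#' @param displacement Mover displacement in px between the two images.
#'   Kept below the body length so a mover's old and new silhouettes stay
#'   connected in the difference image.
#' @param debris_count Dark static debris blobs.
#' @param seed Integer seed.
#' @param canvas `(height, width)` px (default: an assembled 3x4 well
#'   mosaic of 640x480 tiles).
#' @param body_length,amplitude,thickness Worm body parameters, px.
#' @param background_level,worm_level,noise_sd,scale Rendering parameters.
#' @param interval Seconds between the two images (recorded in the truth).
#' @return List of class `sim_pair`: `img1`, `img2` (`gray_image`), `truth`
#'   (with `n_moving`, `n_still`, per-worm rows).
#' @export
render_lifespan_pair <- function(n_moving, n_still, displacement = 10,
                                 debris_count = 0, seed = 1,
                                 canvas = c(1440, 2560),
                                 body_length = 40, amplitude = 4,
                                 thickness = 3, background_level = 220,
                                 worm_level = 30, noise_sd = 6, scale = 20,
                                 interval = 120) {
  stopifnot(n_moving >= 0, n_still >= 0)
  if (n_moving > 0 && displacement <= 0)
    stop("`displacement` must be > 0 when movers are present")
  with_seed(seed, {
    proto <- sim_worm(body_length = body_length, amplitude = amplitude,
                      thickness = thickness)
    rad <- worm_radius(proto) + displacement
    centers <- matrix(numeric(0), 0, 2)
    place_free <- function(min_sep) {
      for (try in seq_len(1000L)) {
        p <- c(stats::runif(1, rad + 2, canvas[1] - rad - 1),
               stats::runif(1, rad + 2, canvas[2] - rad - 1))
        if (nrow(centers) == 0 ||
            min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)) >=
            min_sep) return(p)
      }
      stop("plate too crowded to place all worms without overlap")
    }
    n <- n_moving + n_still
    worms <- vector("list", n)
    for (i in seq_len(n)) {
      p <- place_free(2 * rad + 6)
      centers <- rbind(centers, p)
      worms[[i]] <- sim_worm(
        id = i, start = p, heading = stats::runif(1, 0, 2 * pi),
        speed = 0, body_length = body_length, amplitude = amplitude,
        phase = stats::runif(1, 0, 2 * pi), thickness = thickness)
    }
    moving <- seq_len(n) <= n_moving

    img1 <- matrix(background_level, canvas[1], canvas[2])
    img2 <- img1
    for (i in seq_len(n)) {
      wm <- worms[[i]]
      pts1 <- worm_midline(wm$start, wm$heading, wm$u_extent, wm$amplitude,
                           wm$wavelength, wm$phase)
      img1 <- stamp_band(img1, pts1, wm$thickness, worm_level)
      if (moving[i]) {
        p2 <- wm$start + displacement * c(sin(wm$heading), cos(wm$heading))
        pts2 <- worm_midline(p2, wm$heading, wm$u_extent, wm$amplitude,
                             wm$wavelength, wm$phase + 2.0)
      } else {
        pts2 <- pts1
      }
      img2 <- stamp_band(img2, pts2, wm$thickness, worm_level)
    }
    for (k in seq_len(debris_count)) {
      p <- place_free(2 * rad + 10)
      centers <- rbind(centers, p)
      lev <- stats::runif(1, 10, 60)
      for (s in seq_len(sample(3:7, 1))) {
        q <- p + stats::runif(2, -10, 10)
        a <- stats::runif(1, 4, 12)
        img1 <- draw_ellipse(img1, q, a, a * stats::runif(1, 0.6, 1), 0, lev)
        img2 <- draw_ellipse(img2, q, a, a * stats::runif(1, 0.6, 1), 0, lev)
      }
    }
    truth <- data.frame(
      id = seq_len(n), moving = moving,
      center_r = vapply(worms, function(w) w$start[1], numeric(1)),
      center_c = vapply(worms, function(w) w$start[2], numeric(1)))
    structure(list(img1 = gray_image(add_noise(img1, noise_sd), scale),
                   img2 = gray_image(add_noise(img2, noise_sd), scale),
                   truth = list(n_moving = n_moving, n_still = n_still,
                                interval = interval, worms = truth),
                   params = list(kind = "lifespan_pair", seed = seed,
                                 displacement = displacement)),
              class = "sim_pair")
  })
}

#' @export
print.sim_plate <- function(x, ...) {
  cat(sprintf("<sim_plate> %s, %dx%d px\n", x$params$kind,
              x$image$height, x$image$width))
  invisible(x)
}

#' @export
print.sim_pair <- function(x, ...) {
  cat(sprintf("<sim_pair> %dx%d px, %d moving / %d still worm(s)\n",
              x$img1$height, x$img1$width,
              x$truth$n_moving, x$truth$n_still))
  invisible(x)
}

#' Write a simulated plate or pair to disk with its manifest
#'
#' @param x A `sim_plate` or `sim_pair`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_sim_asset <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "sim_pair")) {
    write_gray_image(x$img1, file.path(out_dir, "scan1.png"))
    write_gray_image(x$img2, file.path(out_dir, "scan2.png"))
  } else {
    write_gray_image(x$image, file.path(out_dir, "plate.png"))
  }
  jsonlite::write_json(list(truth = x$truth, params = x$params),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
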