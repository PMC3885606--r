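# Multi-threshold egg counting.
#
# Five stages: (1) find isolated single eggs with edge detection and
# contour filling; (2) derive reference priors (typical egg gray value and
# area) from those singles; (3) binarize the image at many global gray
# levels; (4) morphology-filter the blobs of every binary image against
# the priors, splitting small aggregates into their equivalent egg counts;
# (5) cluster the pooled detections across levels, keeping locations seen
# at enough distinct levels. Thresholding at many levels recovers faint
# eggs that only separate from background in a narrow intensity band.

#' Parameters for egg counting
#'
#' @param levels Global threshold gray values; at least 10.
#' @param min_occurrences A clustered detection must appear at this many
#'   distinct threshold levels to count as an egg.
#' @param merge_radius Detections closer than this (px) are considered the
#'   same egg; `NULL` = 0.35 x the equivalent diameter of the reference
#'   egg area (small enough that touching eggs stay distinct).
#' @param area_band_factors Single-egg area band as multiples of the
#'   reference area.
#' @param clump_max_factor Aggregates up to this multiple of the reference
#'   area are split into `round(area / ref_area)` eggs.
#' @param eccentricity_band Ellipse-likeness band for single eggs.
#' @param min_solidity Solidity floor (area / convex hull area) for single
#'   eggs during prior estimation.
#' @param canny_low,canny_high,max_gap Edge detection and contour repair
#'   settings for the single-egg stage.
#' @param scale Micrometers per pixel of egg-assay images (egg plates are
#'   imaged at higher magnification than whole-well scans; about 5 um/px
#'   puts a 50 x 30 um egg at a workable 10 x 6 px).
#' @return An `egg_params` list.
#' @export
egg_params <- function(levels = seq(30, 230, by = 10), min_occurrences = 3,
                       merge_radius = NULL,
                       area_band_factors = c(0.5, 1.5),
                       clump_max_factor = 5,
                       eccentricity_band = c(0.35, 0.92),
                       min_solidity = 0.85,
                       canny_low = 15, canny_high = 40, max_gap = 2,
                       scale = 5) {
  if (length(levels) < 10)
    stop("at least 10 threshold levels are required")
  stopifnot(min_occurrences >= 1, is.null(merge_radius) || merge_radius > 0,
            scale > 0)
  structure(list(levels = levels, min_occurrences = min_occurrences,
                 scale = scale,
                 merge_radius = merge_radius,
                 area_band_factors = area_band_factors,
                 clump_max_factor = clump_max_factor,
                 eccentricity_band = eccentricity_band,
                 min_solidity = min_solidity,
                 canny_low = canny_low, canny_high = canny_high,
                 max_gap = max_gap),
            class = "egg_params")
}

region_solidity <- function(labels, regs) {
  nr <- nrow(labels)
  vapply(seq_len(nrow(regs)), function(i) {
    idx <- which(labels == regs$label[i])
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    if (length(idx) < 4) return(1)
    h <- grDevices::chull(cols, rows)
    hx <- cols[h]; hy <- rows[h]
    hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    # hull of pixel centers underestimates the pixelated blob; pad by the
    # half-pixel boundary band
    hull_area <- hull_area + length(h) * 0.5
    min(length(idx) / max(hull_area, 1), 1)
  }, numeric(1))
}

#' Locate isolated single eggs and derive detection priors
#'
#' Canny edge detection, contour gap closing and hole filling, labeling,
#' then an egg-template morphology filter (plausible area, ellipse-like
#' eccentricity, high solidity). The surviving isolated blobs define the
#' reference egg: `ref_area` and `ref_gray` are their medians.
#'
#' @param img A `gray_image`.
#' @param p An [egg_params()].
#' @param plausible_area Broad area range (px) for a single egg candidate.
#' @return List of class `egg_priors`: `ref_gray`, `ref_area`, `area_band`,
#'   `ellipse_band`, `singles` (regions), `n_candidates` (all prefilter
#'   blobs), `low_confidence` (TRUE when only one single was found).
#'   Errors: condition class `wv_empty_plate` when no plausible candidate
#'   blob exists at all, `wv_no_priors` when candidates exist but none
#'   qualifies as a single egg.
#' @export
find_single_eggs <- function(img, p = egg_params(),
                             plausible_area = c(15, 400)) {
  px <- as_pixels(img)
  edges <- canny_edges(img, low = p$canny_low, high = p$canny_high)
  filled <- fill_gaps_and_holes(edges, max_gap = p$max_gap)
  regs <- label_regions(filled, 8, intensity = img)
  cand <- regs[regs$area >= plausible_area[1] &
                 regs$area <= plausible_area[2] &
                 regs$mean_intensity < mean(px), , drop = FALSE]
  if (nrow(cand)) {
    # thin curvilinear marks (worm tracks) are not plausible eggs at all
    ax <- region_axes(attr(regs, "labels"), cand)
    cand <- cand[ax[, "width"] >= 3, , drop = FALSE]
  }
  if (nrow(cand) == 0) {
    cond <- structure(
      class = c("wv_empty_plate", "error", "condition"),
      list(message = "no candidate objects found on the plate",
           call = sys.call()))
    stop(cond)
  }
  sol <- region_solidity(attr(regs, "labels"), cand)
  # an egg is a true filled ellipse: its pixel area must agree with the
  # area of its moment-equivalent ellipse (lumpy debris does not)
  ell_fit <- cand$area / pmax(pi * cand$semi_major * cand$semi_minor, 1)
  # C. elegans eggs are stereotyped (about 50 x 30 um); with a calibrated
  # image this bounds a plausible single-egg footprint
  scale <- if (inherits(img, "gray_image")) img$scale else 5
  nominal_area <- pi * (25 / scale) * (15 / scale)
  size_ok <- cand$area >= 0.35 * nominal_area &
    cand$area <= 2.5 * nominal_area
  singles <- cand[size_ok &
                    cand$eccentricity >= p$eccentricity_band[1] &
                    cand$eccentricity <= p$eccentricity_band[2] &
                    sol >= p$min_solidity &
                    abs(ell_fit - 1) <= 0.18, , drop = FALSE]
  if (nrow(singles) == 0) {
    cond <- structure(
      class = c("wv_no_priors", "error", "condition"),
      list(message = paste(
        "no isolated single egg found; egg priors cannot be estimated",
        "(counting aborted rather than reporting a silent zero)"),
        call = sys.call()))
    stop(cond)
  }
  # keep the dominant size/intensity consensus group: eggs on one plate are
  # near-uniform while debris fragments are heterogeneous, so the largest
  # mutually-similar group is the egg population
  if (nrow(singles) > 2) {
    support <- vapply(seq_len(nrow(singles)), function(i) {
      sum(abs(singles$area - singles$area[i]) / singles$area[i] < 0.35 &
            abs(singles$mean_intensity - singles$mean_intensity[i]) < 60)
    }, numeric(1))
    anchor <- which.max(support)
    singles <- singles[
      abs(singles$area - singles$area[anchor]) / singles$area[anchor] < 0.35 &
        abs(singles$mean_intensity - singles$mean_intensity[anchor]) < 60, ,
      drop = FALSE]
  }
  # the filled Canny contour overestimates the egg footprint by the closing
  # dilation; re-measure each single at its own midpoint threshold so the
  # reference area matches what global thresholding will see
  bg <- stats::median(px)
  refined <- vapply(seq_len(nrow(singles)), function(i) {
    rs <- max(singles$min_row[i] - 2, 1):min(singles$max_row[i] + 2, nrow(px))
    cs <- max(singles$min_col[i] - 2, 1):min(singles$max_col[i] + 2, ncol(px))
    sum(px[rs, cs] < (singles$mean_intensity[i] + bg) / 2)
  }, numeric(1))
  ref_area <- stats::median(refined)
  ref_gray <- stats::median(singles$mean_intensity)
  gray_range <- range(singles$mean_intensity)
  # narrow the ellipse band to what the plate's own eggs exhibit
  ellipse_band <- c(max(p$eccentricity_band[1], min(singles$eccentricity) - 0.08),
                    min(p$eccentricity_band[2], max(singles$eccentricity) + 0.05))
  structure(list(ref_gray = ref_gray, ref_area = ref_area,
                 area_band = p$area_band_factors * ref_area,
                 ellipse_band = ellipse_band,
                 gray_range = gray_range,
                 singles = singles, n_candidates = nrow(cand),
                 low_confidence = nrow(singles) == 1),
            class = "egg_priors")
}

#' @export
print.egg_priors <- function(x, ...) {
  cat(sprintf(
    "<egg_priors> ref area %.0f px, ref gray %.0f, from %d single(s)%s\n",
    x$ref_area, x$ref_gray, nrow(x$singles),
    if (x$low_confidence) " [low confidence: n=1]" else ""))
  invisible(x)
}

# Moment-based major-axis descriptors for selected labels.
region_axes <- function(labels, regs) {
  nr <- nrow(labels)
  out <- matrix(NA_real_, nrow(regs), 3,
                dimnames = list(NULL, c("major_len", "theta", "width")))
  for (i in seq_len(nrow(regs))) {
    idx <- which(labels == regs$label[i])
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    dr <- rows - mean(rows); dc <- cols - mean(cols)
    mu20 <- mean(dr^2); mu02 <- mean(dc^2); mu11 <- mean(dr * dc)
    theta <- 0.5 * atan2(2 * mu11, mu02 - mu20)
    proj <- dc * cos(theta) + dr * sin(theta)
    major <- diff(range(proj)) + 1
    out[i, ] <- c(major, theta, length(idx) / major)
  }
  out
}

#' Detect egg candidates at many global thresholds
#'
#' For every gray level, binarizes the image globally (`pixel < level`),
#' labels the blobs, and keeps those matching the reference egg: singles
#' with area inside the prior band and ellipse-like eccentricity, and small
#' aggregates (up to `clump_max_factor` x the reference area, with
#' egg-like width) split into `round(area / ref_area)` detections spaced
#' along the blob's major axis.
#'
#' @param img A `gray_image`.
#' @param priors An `egg_priors`.
#' @param p An [egg_params()] (supplies the levels and bands).
#' @return Data frame of raw detections: `centroid_r`, `centroid_c`,
#'   `area`, `level`, `from_clump`.
#' @export
multi_threshold_detect <- function(img, priors, p = egg_params()) {
  if (length(p$levels) < 10) stop("at least 10 threshold levels required")
  px <- as_pixels(img)
  ref <- priors$ref_area
  ref_width <- 2 * sqrt(ref / pi / 1.54)   # minor diameter of a 2:1.3 ellipse
  det <- vector("list", length(p$levels))
  gray_lo <- if (!is.null(priors$gray_range)) priors$gray_range[1] - 25 else 0
  for (li in seq_along(p$levels)) {
    lev <- p$levels[li]
    mask <- px < lev
    if (!any(mask) || mean(mask) > 0.5) next   # blank or background flood
    regs <- label_regions(binary_image(mask), 8, intensity = px)
    regs <- regs[regs$area >= priors$area_band[1] &
                   regs$area <= p$clump_max_factor * ref + ref &
                   # darker than any egg this plate exhibits = debris
                   regs$mean_intensity >= gray_lo, , drop = FALSE]
    if (!nrow(regs)) next
    fit <- regs$area / pmax(pi * regs$semi_major * regs$semi_minor, 1)
    singles <- regs[regs$area <= priors$area_band[2] &
                      regs$eccentricity >= priors$ellipse_band[1] &
                      regs$eccentricity <= priors$ellipse_band[2] &
                      abs(fit - 1) <= 0.25, , drop = FALSE]
    clumps <- regs[regs$area > priors$area_band[2] &
                     regs$area <= p$clump_max_factor * ref, , drop = FALSE]
    rows <- list()
    if (nrow(singles))
      rows[[1]] <- data.frame(centroid_r = singles$centroid_r,
                              centroid_c = singles$centroid_c,
                              area = singles$area, level = lev,
                              from_clump = FALSE)
    if (nrow(clumps)) {
      lbl <- attr(regs, "labels")
      # an aggregate of touching eggs is a chain roughly one egg wide:
      # its distance-transform half-width matches the egg minor radius.
      # Curvilinear track marks are far thinner, lumpy debris far thicker.
      ref_b <- sqrt(ref / pi / 1.54)   # reference minor semi-axis
      halfw <- vapply(seq_len(nrow(clumps)), function(i) {
        cr <- crop_region(lbl, clumps[i, ], pad = 1L)
        max(EBImage::distmap(cr$mask * 1))
      }, numeric(1))
      k_est <- pmax(round(clumps$area / ref), 1)
      # a chain of k eggs cannot extend much beyond k egg major diameters;
      # an egg fused with a long track mark can, and must not be split
      ref_major <- 2 * 1.54 * ref_b
      ax0 <- region_axes(lbl, clumps)
      keep <- halfw >= 0.6 * ref_b & halfw <= 1.45 * ref_b &
        ax0[, "major_len"] <= 1.35 * k_est * ref_major &
        # k eggs cannot pack into much less than half a k-chain's extent
        (k_est <= 2 | ax0[, "major_len"] >= 0.45 * k_est * ref_major)
      clumps <- clumps[keep, , drop = FALSE]
      ax <- ax0[keep, , drop = FALSE]
      if (nrow(clumps)) {
        split_rows <- lapply(seq_len(nrow(clumps)), function(i) {
          k <- max(round(clumps$area[i] / ref), 1)
          if (k == 1) {
            data.frame(centroid_r = clumps$centroid_r[i],
                       centroid_c = clumps$centroid_c[i],
                       area = clumps$area[i], level = lev,
                       from_clump = FALSE)
          } else {
            # k split points spread along the blob's major axis
            off <- (seq_len(k) - (k + 1) / 2) * (ax[i, "major_len"] / k)
            data.frame(
              centroid_r = clumps$centroid_r[i] + off * sin(ax[i, "theta"]),
              centroid_c = clumps$centroid_c[i] + off * cos(ax[i, "theta"]),
              area = clumps$area[i] / k, level = lev, from_clump = TRUE)
          }
        })
        rows[[2]] <- do.call(rbind, split_rows)
      }
    }
    if (length(rows)) det[[li]] <- do.call(rbind, rows)
  }
  det <- det[!vapply(det, is.null, logical(1))]
  if (!length(det))
    return(data.frame(centroid_r = numeric(), centroid_c = numeric(),
                      area = numeric(), level = numeric(),
                      from_clump = logical()))
  do.call(rbind, det)
}

#' Cluster raw multi-threshold detections into unique eggs
#'
#' Single-linkage grouping of detections within `merge_radius` of each
#' other; each group becomes one candidate egg whose occurrence count is
#' the number of distinct threshold levels contributing to it. Groups seen
#' at fewer than `min_occurrences` levels are discarded as spurious.
#'
#' @param raw Data frame from [multi_threshold_detect()].
#' @param priors An `egg_priors`.
#' @param p An [egg_params()].
#' @param level_floor Optional gray level every kept cluster must reach: an
#'   isolated egg stays its own blob until the threshold nearly reaches the
#'   background, whereas an egg-sized lobe of a larger dark mass merges
#'   into its parent once the threshold passes the mass's gray value. Pass
#'   `background - 45` (computed by [count_eggs()]) to drop such lobes;
#'   `NULL` disables the check.
#' @return Object of class `egg_count_result`: `n_eggs`, `detections`
#'   (centroid, area, occurrences, source levels), `n_candidates_prefilter`,
#'   `priors_used`.
#' @export
cluster_detections <- function(raw, priors, p = egg_params(),
                               level_floor = NULL) {
  merge_radius <- p$merge_radius
  if (is.null(merge_radius))
    merge_radius <- 0.5 * 2 * sqrt(priors$ref_area / pi)
  if (merge_radius <= 0) stop("`merge_radius` must be > 0")

  n <- nrow(raw)
  if (n == 0) {
    return(structure(list(n_eggs = 0L,
                          detections = data.frame(
                            centroid_r = numeric(), centroid_c = numeric(),
                            area = numeric(), occurrences = integer()),
                          source_levels = list(),
                          n_candidates_prefilter = 0L,
                          priors_used = priors),
                     class = "egg_count_result"))
  }
  # greedy density-seeded grouping: repeatedly seed a cluster at the
  # detection with the most neighbors within merge_radius, claim those
  # neighbors, and remove them. Unlike single linkage this cannot chain
  # two adjacent touching eggs together through intermediate jittered
  # split points.
  r <- raw$centroid_r; c <- raw$centroid_c
  alive <- rep(TRUE, n)
  groups <- list()
  while (any(alive)) {
    ia <- which(alive)
    d2 <- (outer(r[ia], r[ia], "-")^2 + outer(c[ia], c[ia], "-")^2)
    counts <- rowSums(d2 <= merge_radius^2)
    seed <- which.max(counts)
    claimed <- ia[d2[seed, ] <= merge_radius^2]
    groups[[length(groups) + 1L]] <- claimed
    alive[claimed] <- FALSE
  }

  det <- do.call(rbind, lapply(groups, function(g) {
    data.frame(centroid_r = mean(raw$centroid_r[g]),
               centroid_c = mean(raw$centroid_c[g]),
               area = stats::median(raw$area[g]),
               occurrences = length(unique(raw$level[g])))
  }))
  src <- lapply(groups, function(g) sort(unique(raw$level[g])))
  keep <- det$occurrences >= p$min_occurrences
  if (!is.null(level_floor)) {
    top <- vapply(src, max, numeric(1))
    keep <- keep & top >= level_floor
  }
  structure(list(n_eggs = sum(keep),
                 detections = det[keep, , drop = FALSE],
                 source_levels = src[keep],
                 n_candidates_prefilter = nrow(det),
                 priors_used = priors),
            class = "egg_count_result")
}

#' Count eggs in a plate image
#'
#' Full pipeline: single-egg prior estimation, multi-threshold detection,
#' and clustering. An image with no plausible egg-like objects at all
#' yields a zero count; an image where candidate blobs exist but no
#' isolated single egg can anchor the priors aborts with an explicit
#' error (condition class `wv_no_priors`).
#'
#' @param img A `gray_image`.
#' @param p An [egg_params()].
#' @return An `egg_count_result` (see [cluster_detections()]).
#' @export
count_eggs <- function(img, p = egg_params()) {
  priors <- tryCatch(find_single_eggs(img, p),
                     wv_empty_plate = function(e) NULL)
  if (is.null(priors)) {
    return(structure(list(n_eggs = 0L,
                          detections = data.frame(
                            centroid_r = numeric(), centroid_c = numeric(),
                            area = numeric(), occurrences = integer()),
                          source_levels = list(),
                          n_candidates_prefilter = 0L,
                          priors_used = NULL),
                     class = "egg_count_result"))
  }
  raw <- multi_threshold_detect(img, priors, p)
  bg <- stats::median(as_pixels(img))
  cluster_detections(raw, priors, p, level_floor = bg - 45)
}

#' @export
print.egg_count_result <- function(x, ...) {
  cat(sprintf("<egg_count_result> %d egg(s) (%d raw cluster(s) before the occurrence filter)\n",
              x$n_eggs, x$n_candidates_prefilter))
  invisible(x)
}

#' Egg-laying rate from a count
#'
#' @param n_eggs Egg count.
#' @param n_worms Number of laying adults.
#' @param minutes Incubation time in minutes (e.g. 90 for the standard
#'   90-minute assay).
#' @return Eggs per worm per hour.
#' @export
egg_laying_rate <- function(n_eggs, n_worms, minutes = 90) {
  stopifnot(n_worms > 0, minutes > 0)
  n_eggs / n_worms / (minutes / 60)
}
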