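# Skeleton-based body-length measurement from still images.

#' Parameters for body-length measurement
#'
#' @param min_area,max_area Region area limits, px.
#' @param min_bbox_side,max_bbox_side Bounding-box side limits, px.
#' @param fatness_range Accepted band for mean body width
#'   (area / skeleton length), px. Rejects compact blobs (too fat) and
#'   hair-like marks (too thin).
#' @param scale Micrometers per pixel.
#' @param tip_correction Extend each skeleton end along its terminal
#'   direction until it leaves the body mask. Thinning stops roughly half a
#'   body width short of the true head and tail; without the correction
#'   lengths bias low by about one body thickness.
#' @param spur_prune Prune skeleton side branches up to this many px before
#'   judging branchedness (boundary roughness of a thick body leaves short
#'   spurs); see [skeletonize()].
#' @param smooth_window Window (in skeleton pixels) of the local polynomial
#'   smoothing applied to the traced skeleton path before summing step
#'   distances; removes the staircase quantization of the digital curve.
#' @param window,offset_fraction Adaptive-threshold settings.
#' @return A `length_params` list.
#' @export
length_params <- function(min_area = 100, max_area = 4000,
                          min_bbox_side = 10, max_bbox_side = Inf,
                          fatness_range = c(2, 8), scale = 20,
                          tip_correction = TRUE, spur_prune = NULL,
                          smooth_window = 11L, window = NULL,
                          offset_fraction = 0.15) {
  stopifnot(min_area < max_area, fatness_range[1] > 0,
            fatness_range[1] < fatness_range[2], scale > 0)
  structure(list(min_area = min_area, max_area = max_area,
                 min_bbox_side = min_bbox_side,
                 max_bbox_side = max_bbox_side,
                 fatness_range = fatness_range, scale = scale,
                 tip_correction = tip_correction, spur_prune = spur_prune,
                 smooth_window = as.integer(smooth_window),
                 window = window, offset_fraction = offset_fraction),
            class = "length_params")
}

# Extend a traced skeleton path beyond an endpoint along the local terminal
# direction until the body mask is left. Returns the added length in px.
extend_tip <- function(mask, path, from_start, max_steps) {
  n <- nrow(path)
  if (n < 4) return(0)
  k <- min(5L, n - 1L)
  if (from_start) {
    tip <- path[1, ]; inner <- path[1 + k, ]
  } else {
    tip <- path[n, ]; inner <- path[n - k, ]
  }
  dirv <- tip - inner
  nv <- sqrt(sum(dirv^2))
  if (nv == 0) return(0)
  dirv <- dirv / nv
  added <- 0
  pos <- tip
  for (s in seq_len(max_steps * 2)) {
    cand <- pos + dirv * 0.5
    rc <- round(cand)
    if (rc[1] < 1 || rc[1] > nrow(mask) || rc[2] < 1 || rc[2] > ncol(mask))
      break
    if (!mask[rc[1], rc[2]]) break
    pos <- cand
    added <- added + 0.5
  }
  added
}

# Length of one worm candidate from its cropped mask. Returns a list with
# the skeleton and the measured length, or a reject reason.
measure_candidate <- function(mask, p) {
  # light mask cleanup: fill pinholes that would branch the skeleton
  m <- EBImage::fillHull(mask * 1) > 0.5
  sk <- tryCatch(skeletonize(m, prune = 0), error = function(e) NULL)
  if (is.null(sk)) return(list(reason = "too_thin"))
  # robust body half-width: median ridge height along the raw skeleton.
  # (The max would be inflated by an attached egg or particle, which must
  # not raise its own pruning threshold.)
  dm <- EBImage::distmap(m * 1)
  half_w <- stats::median(dm[sk$pixels])
  if (sk$branch_count > 0) {
    prune <- if (is.null(p$spur_prune)) {
      # boundary-roughness spurs run about half a body width; forks from
      # an attached egg or particle run a full width or more and must
      # survive pruning so the candidate is rejected as branched
      max(4L, as.integer(ceiling(1.4 * half_w)) + 2L)
    } else p$spur_prune
    skm <- matrix(FALSE, nrow(m), ncol(m))
    skm[sk$pixels] <- TRUE
    sk <- analyze_skeleton(prune_spurs(skm, prune))
  }
  if (sk$branch_count > 0) return(list(reason = "branched", skeleton = sk))
  if (!sk$traceable || nrow(sk$path) < 5)
    return(list(reason = "too_fat", skeleton = sk))

  path <- sk$path
  sm <- piecewise_poly_smooth(path, window = min(p$smooth_window, nrow(path)),
                              overlap = max(p$smooth_window %/% 2, 1L))
  len <- polyline_length(sm)
  if (p$tip_correction) {
    # thinning stops near the center of each rounded tip, half a body
    # width inside the silhouette edge: extend to the edge, then take
    # the rounded-cap geometry back off
    w1 <- extend_tip(m, path, TRUE, ceiling(half_w * 3))
    w2 <- extend_tip(m, path, FALSE, ceiling(half_w * 3))
    len <- len + max(w1 - half_w, 0) + max(w2 - half_w, 0)
  }
  list(skeleton = sk, length_px = len, reason = "none")
}

#' Measure worm body lengths in a still image
#'
#' Binarize, label, filter candidates by area and bounding box, skeletonize
#' each candidate, reject branched skeletons (overlapping worms, worms
#' touching eggs or debris), measure the remaining skeleton curves, and
#' apply the fatness filter (area per skeleton length). All candidates are
#' returned, valid or not, so rejections can be audited downstream.
#'
#' The reported length is the Euclidean length of the traced skeleton path
#' after local polynomial smoothing (which removes pixel-staircase
#' quantization), plus an optional tip-extension correction at both ends;
#' see [length_params()].
#'
#' @param img A calibrated `gray_image`.
#' @param p A [length_params()]; its `scale` defaults to the image's.
#' @return A data frame of class `worm_measurements`: one row per candidate
#'   with region descriptors, `length_px`, `length_um`, `fatness`, `valid`
#'   and `reject_reason` (`"none"`, `"branched"`, `"too_small"`,
#'   `"too_large"`, `"too_fat"`, `"too_thin"`). Skeletons of measured
#'   candidates are attached as `attr(, "skeletons")`.
#' @export
measure_worms <- function(img, p = length_params()) {
  if (inherits(img, "gray_image") && !is.null(img$scale)) p$scale <- img$scale
  bin <- adaptive_threshold(img, window = p$window,
                            offset_fraction = p$offset_fraction)
  regs <- label_regions(bin, 8)
  lbl <- attr(regs, "labels")

  out <- as.data.frame(regs)
  out$length_px <- rep(NA_real_, nrow(out))
  out$fatness <- rep(NA_real_, nrow(out))
  out$valid <- rep(FALSE, nrow(out))
  out$reject_reason <- rep("none", nrow(out))
  skeletons <- vector("list", nrow(out))

  for (i in seq_len(nrow(out))) {
    side <- c(out$max_row[i] - out$min_row[i] + 1,
              out$max_col[i] - out$min_col[i] + 1)
    if (out$area[i] < p$min_area || max(side) < p$min_bbox_side) {
      out$reject_reason[i] <- "too_small"; next
    }
    if (out$area[i] > p$max_area || max(side) > p$max_bbox_side) {
      out$reject_reason[i] <- "too_large"; next
    }
    cr <- crop_region(lbl, out[i, ], pad = 3L)
    res <- measure_candidate(cr$mask, p)
    if (!is.null(res$skeleton)) skeletons[[i]] <- res$skeleton
    if (res$reason != "none") { out$reject_reason[i] <- res$reason; next }
    out$length_px[i] <- res$length_px
    fat <- out$area[i] / res$length_px
    out$fatness[i] <- fat
    if (fat > p$fatness_range[2]) { out$reject_reason[i] <- "too_fat"; next }
    if (fat < p$fatness_range[1]) { out$reject_reason[i] <- "too_thin"; next }
    out$valid[i] <- TRUE
  }
  out$length_um <- out$length_px * p$scale
  attr(out, "skeletons") <- skeletons
  attr(out, "labels") <- lbl
  class(out) <- c("worm_measurements", "data.frame")
  out
}

#' @export
print.worm_measurements <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("<worm_measurements> %d candidate(s), %d valid\n", nrow(x), nv))
  if (nv) {
    v <- x[x$valid, ]
    cat(sprintf("  lengths: %.0f-%.0f um (median %.0f)\n",
                min(v$length_um), max(v$length_um),
                stats::median(v$length_um)))
  }
  invisible(x)
}
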