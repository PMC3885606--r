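# Moving-worm counting from time-lapse pairs and survival post-processing.

#' Parameters for moving-worm counting
#'
#' @param min_worm_area,max_worm_area Acceptable worm region area, px.
#'   Defaults bracket L4-adult animals at 20 um/px.
#' @param min_changed_pixels Absolute floor on changed (difference-image
#'   foreground) pixels inside a worm ROI for it to count as moving.
#' @param min_changed_fraction Changed-pixel requirement as a fraction of
#'   the ROI area; the effective threshold per ROI is
#'   `max(min_changed_pixels, min_changed_fraction * area)`.
#' @param interval Seconds between the two scans (default 120).
#' @param window,offset_fraction Adaptive-threshold settings passed through
#'   to [adaptive_threshold()] (`NULL` window = automatic).
#' @return A `lifespan_params` list.
#' @export
lifespan_params <- function(min_worm_area = 40, max_worm_area = 2000,
                            min_changed_pixels = 10,
                            min_changed_fraction = 0.25,
                            interval = 120, window = NULL,
                            offset_fraction = 0.15) {
  stopifnot(min_worm_area > 0, min_worm_area < max_worm_area,
            min_changed_pixels >= 1, min_changed_fraction >= 0,
            min_changed_fraction <= 1, interval > 0)
  structure(list(min_worm_area = min_worm_area,
                 max_worm_area = max_worm_area,
                 min_changed_pixels = min_changed_pixels,
                 min_changed_fraction = min_changed_fraction,
                 interval = interval, window = window,
                 offset_fraction = offset_fraction),
            class = "lifespan_params")
}

#' Count moving worms from a two-image time-lapse pair
#'
#' Living worms move or change posture between two scans taken a couple of
#' minutes apart. The absolute difference of the two images is binarized by
#' adaptive thresholding so changed pixels become foreground. Candidate
#' worm regions are detected independently in the second image; a candidate
#' is moving when enough changed pixels fall inside it. Finally,
#' worm-sized connected components of the difference image that do not
#' touch any candidate region are added as extra movers - this recovers
#' worms whose silhouette merged with large dark debris in the second image
#' and therefore never became a size-valid candidate.
#'
#' @param img1,img2 `gray_image`s of the same field of view, same shape.
#' @param p A [lifespan_params()].
#' @return Object of class `moving_worm_result`: `n_moving`, `rois`
#'   (candidate regions from image 2), `moving_flags`, `extra_movers`
#'   (recovered difference-only regions), and `diff_mask`.
#' @export
count_moving_worms <- function(img1, img2, p = lifespan_params()) {
  px1 <- as_pixels(img1); px2 <- as_pixels(img2)
  if (!all(dim(px1) == dim(px2)))
    stop("the two images must have identical dimensions")

  d <- abs(px1 - px2)
  diff_bin <- adaptive_threshold(gray_image(d), window = p$window,
                                 offset_fraction = p$offset_fraction,
                                 dark_objects = FALSE)
  diff_mask <- diff_bin$mask

  bin2 <- adaptive_threshold(img2, window = p$window,
                             offset_fraction = p$offset_fraction)
  regs <- label_regions(bin2, 8)
  rois <- regs[regs$area >= p$min_worm_area & regs$area <= p$max_worm_area, ,
               drop = FALSE]

  moving_flags <- logical(nrow(rois))
  if (nrow(rois)) {
    lbl <- attr(regs, "labels")
    idx <- which(lbl > 0L)
    changed_by_label <- rowsum(as.numeric(diff_mask[idx]), lbl[idx])
    lookup <- stats::setNames(as.vector(changed_by_label),
                              rownames(changed_by_label))
    changed_in <- unname(lookup[as.character(rois$label)])
    changed_in[is.na(changed_in)] <- 0
    need <- pmax(p$min_changed_pixels,
                 p$min_changed_fraction * rois$area)
    moving_flags <- changed_in >= need
  }

  dregs_all <- label_regions(binary_image(diff_mask), 8)
  dlbl <- attr(dregs_all, "labels")
  # a recovered mover must be dark in the second image: the worm is there,
  # just fused with debris. Old-position-only difference blobs (the worm
  # left) sit on background in image 2 and must not be double counted.
  fg_frac <- numeric(nrow(dregs_all))
  if (nrow(dregs_all)) {
    idx2 <- which(dlbl > 0L)
    fg_by_label <- rowsum(as.numeric(bin2$mask[idx2]), dlbl[idx2])
    fg_frac <- as.vector(fg_by_label)[match(dregs_all$label,
                                            as.integer(rownames(fg_by_label)))] /
      dregs_all$area
  }
  dregs <- dregs_all[dregs_all$area >= p$min_worm_area &
                       dregs_all$area <= 2 * p$max_worm_area &
                       fg_frac >= 0.3, , drop = FALSE]
  extra <- dregs[0, , drop = FALSE]
  if (nrow(dregs) && nrow(rois)) {
    free <- vapply(seq_len(nrow(dregs)), function(i) {
      a <- c(min_row = dregs$min_row[i], max_row = dregs$max_row[i],
             min_col = dregs$min_col[i], max_col = dregs$max_col[i])
      for (j in seq_len(nrow(rois))) {
        b <- c(min_row = rois$min_row[j], max_row = rois$max_row[j],
               min_col = rois$min_col[j], max_col = rois$max_col[j])
        if (bbox_intersects(a, b)) return(FALSE)
      }
      TRUE
    }, logical(1))
    extra <- dregs[free, , drop = FALSE]
  } else if (nrow(dregs)) {
    extra <- dregs
  }

  structure(list(n_moving = sum(moving_flags) + nrow(extra),
                 rois = rois, moving_flags = moving_flags,
                 extra_movers = extra, diff_mask = diff_mask),
            class = "moving_worm_result")
}

#' @export
print.moving_worm_result <- function(x, ...) {
  cat(sprintf(
    "<moving_worm_result> %d moving (%d flagged ROI + %d recovered), %d candidate ROI(s)\n",
    x$n_moving, sum(x$moving_flags), nrow(x$extra_movers), nrow(x$rois)))
  invisible(x)
}

#' Step-wise decrease filter for daily living-worm counts
#'
#' Detection noise can make a later day's count exceed an earlier day's,
#' which is impossible for a sealed (FUdR-treated) population. The filter
#' raises each day's count to the maximum of all later counts - the
#' right-to-left running maximum - producing a non-increasing series. The
#' operation is idempotent.
#'
#' @param raw_counts Integer vector of daily living-worm counts (>= 0).
#' @return Filtered counts, same length.
#' @examples
#' stepwise_decrease_filter(c(8, 10, 6, 7, 2))  # 10 10 7 7 2
#' @export
stepwise_decrease_filter <- function(raw_counts) {
  if (!length(raw_counts)) return(raw_counts)
  if (any(raw_counts < 0)) stop("counts must be non-negative")
  rev(cummax(rev(raw_counts)))
}

#' Summarize a filtered survival series
#'
#' Converts a non-increasing daily living-worm series into a death-day
#' distribution and mean lifespan. Deaths are assigned to the day the count
#' drops (the scan that first detects the transition). Day 0 is the first
#' day of adulthood.
#'
#' @param filtered_counts Non-increasing living-worm counts (apply
#'   [stepwise_decrease_filter()] first).
#' @param days Strictly increasing integer day labels, same length.
#' @return Object of class `survival_series`: `days`, `counts`,
#'   `deaths_per_day`, `survival_fraction`, `mean_lifespan` (NA when no
#'   deaths were observed), and `censored` (TRUE when worms remain alive at
#'   the end of the series).
#' @examples
#' s <- survival_summary(c(10, 10, 6, 2, 0), 0:4)
#' s$mean_lifespan  # 2.8
#' @export
survival_summary <- function(filtered_counts, days = seq_along(filtered_counts) - 1) {
  if (length(filtered_counts) != length(days))
    stop("`filtered_counts` and `days` must have equal length")
  if (is.unsorted(days, strictly = TRUE))
    stop("`days` must be strictly increasing")
  if (any(diff(filtered_counts) > 0))
    stop("counts increase over time; apply stepwise_decrease_filter() first")

  deaths <- c(0, -diff(filtered_counts))
  total_deaths <- sum(deaths)
  mean_lifespan <- if (total_deaths > 0)
    sum(days * deaths) / total_deaths else NA_real_
  censored <- filtered_counts[length(filtered_counts)] > 0

  structure(list(days = days, counts = filtered_counts,
                 deaths_per_day = stats::setNames(deaths, days),
                 survival_fraction = if (filtered_counts[1] > 0)
                   filtered_counts / filtered_counts[1] else rep(NA_real_, length(days)),
                 mean_lifespan = mean_lifespan, censored = censored),
            class = "survival_series")
}

#' @export
print.survival_series <- function(x, ...) {
  cat(sprintf("<survival_series> days %d..%d, %d -> %d worms\n",
              min(x$days), max(x$days), x$counts[1],
              x$counts[length(x$counts)]))
  if (is.na(x$mean_lifespan))
    cat("  mean lifespan: undefined (no deaths observed; censored)\n")
  else
    cat(sprintf("  mean lifespan: %.2f days%s\n", x$mean_lifespan,
                if (x$censored) " (right-censored series)" else ""))
  invisible(x)
}

#' @export
plot.survival_series <- function(x, ...) {
  graphics::plot(x$days, x$survival_fraction, type = "s",
                 xlab = "day of adulthood", ylab = "fraction alive",
                 ylim = c(0, 1), ...)
  invisible(x)
}
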