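#' Adaptive local-mean thresholding
#'
#' Binarizes a grayscale image by comparing each pixel against the mean
#' intensity of its local square window, computed in O(1) per pixel from a
#' summed-area (integral) image. A pixel is foreground when it is darker
#' than the local mean by a relative margin:
#' `pixel < local_mean * (1 - offset_fraction)`. Because the reference is
#' local, the rule tolerates shadowed plates and smooth illumination
#' gradients that defeat any single global threshold.
#'
#' @param img A `gray_image` (or numeric intensity matrix).
#' @param window Side of the square averaging window in pixels; odd and
#'   `>= 3`. Default: the image's smaller dimension divided by 8, rounded
#'   to the nearest odd number (a window comfortably larger than a worm,
#'   smaller than illumination structure).
#' @param offset_fraction Relative margin below the local mean required to
#'   call a pixel foreground, in `[0, 1)`. Default 0.15.
#' @param dark_objects If `TRUE` (default) objects are darker than
#'   background, the usual polarity for worms and eggs on bright agar.
#'   If `FALSE` the image is inverted first, selecting bright objects
#'   (e.g. changed pixels of a difference image).
#' @return A `binary_image`.
#' @examples
#' px <- matrix(200, 60, 60)
#' px[20:29, 20:29] <- 40
#' m <- adaptive_threshold(gray_image(px), window = 31)
#' sum(m$mask)  # the 100 dark pixels
#' @export
adaptive_threshold <- function(img, window = NULL, offset_fraction = 0.15,
                               dark_objects = TRUE) {
  px <- as_pixels(img)
  nr <- nrow(px); nc <- ncol(px)
  if (is.null(window)) {
    window <- round(min(nr, nc) / 8)
    if (window %% 2 == 0) window <- window + 1
    window <- max(window, 3)
  }
  if (window < 3 || window %% 2 != 1)
    stop("`window` must be odd and >= 3")
  if (window > nr || window > nc)
    stop(sprintf("window (%d px) exceeds image dimensions (%d x %d)",
                 window, nr, nc))
  if (offset_fraction < 0 || offset_fraction >= 1)
    stop("`offset_fraction` must be in [0, 1)")

  if (!dark_objects) px <- 255 - px
  h <- (window - 1L) / 2L

  # summed-area table with a zero border row/column
  sat <- matrix(0, nr + 1L, nc + 1L)
  sat[-1L, -1L] <- t(apply(apply(px, 2L, cumsum), 1L, cumsum))

  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  win_sum <- sat[r2 + 1L, c2 + 1L, drop = FALSE] -
    sat[r1, c2 + 1L, drop = FALSE] -
    sat[r2 + 1L, c1, drop = FALSE] +
    sat[r1, c1, drop = FALSE]
  win_n <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  local_mean <- win_sum / win_n

  mask <- px < local_mean * (1 - offset_fraction)
  binary_image(mask, foreground = if (dark_objects) "dark" else "bright")
}
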