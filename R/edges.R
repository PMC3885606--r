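# Canny edge detection and contour repair (gap closing + hole filling).

#' Canny edge detection
#'
#' Classic pipeline: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, then hysteresis
#' linking (weak edge pixels are kept only in 8-connected components that
#' contain at least one strong pixel). Used by the egg counter to outline
#' candidate egg contours before gap filling.
#'
#' @param img A `gray_image` or intensity matrix.
#' @param low,high Hysteresis thresholds on gradient magnitude, in intensity
#'   units per pixel; `0 <= low < high <= 255`.
#' @param sigma Gaussian pre-smoothing standard deviation in pixels.
#' @return A `binary_image` of single-pixel-wide edges.
#' @export
canny_edges <- function(img, low = 15, high = 40, sigma = 1) {
  px <- as_pixels(img)
  if (!(low >= 0 && low < high && high <= 255))
    stop("thresholds must satisfy 0 <= low < high <= 255")
  sm <- if (sigma > 0) EBImage::gblur(px, sigma = sigma) else px
  sm <- matrix(as.numeric(sm), nrow(px), ncol(px))

  # Sobel kernels; (r, c) with rows increasing downward
  e <- function(dr, dc) shift_mat(sm, dr, dc, fill = NA)
  n  <- e(1, 0);  s  <- e(-1, 0);  w  <- e(0, 1);  ee <- e(0, -1)
  nw <- e(1, 1);  ne <- e(1, -1);  sw <- e(-1, 1); se <- e(-1, -1)
  # replicate border values where shifts ran off the image
  rep_na <- function(m) { m[is.na(m)] <- sm[is.na(m)]; m }
  n <- rep_na(n); s <- rep_na(s); w <- rep_na(w); ee <- rep_na(ee)
  nw <- rep_na(nw); ne <- rep_na(ne); sw <- rep_na(sw); se <- rep_na(se)
  gx <- (ne + 2 * ee + se) - (nw + 2 * w + sw)   # d/dcol
  gy <- (sw + 2 * s + se) - (nw + 2 * n + ne)    # d/drow
  mag <- sqrt(gx^2 + gy^2) / 4  # normalize Sobel gain to intensity units

  # non-maximum suppression: compare against the two neighbors along the
  # gradient direction, quantized to 0/45/90/135 degrees
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  mshift <- function(dr, dc) shift_mat(mag, dr, dc, fill = 0)
  nmax <- matrix(FALSE, nrow(px), ncol(px))
  # sector 0: gradient ~horizontal (d/dcol) -> compare left/right
  cmp <- list(
    list(mshift(0, 1), mshift(0, -1)),     # 0 deg: compare left/right
    list(mshift(1, 1), mshift(-1, -1)),    # 45 deg: main diagonal
    list(mshift(1, 0), mshift(-1, 0)),     # 90 deg: compare up/down
    list(mshift(1, -1), mshift(-1, 1))     # 135 deg: anti-diagonal
  )
  for (sct in 0:3) {
    sel <- sector == sct
    nmax[sel] <- mag[sel] >= cmp[[sct + 1]][[1]][sel] &
      mag[sel] >= cmp[[sct + 1]][[2]][sel]
  }

  strong <- nmax & mag >= high
  weak <- nmax & mag >= low
  if (!any(strong)) return(binary_image(matrix(FALSE, nrow(px), ncol(px))))
  lbl <- label_mask(weak, 8L)
  keep <- unique(lbl[strong])
  keep <- keep[keep > 0]
  binary_image(matrix(lbl %in% keep, nrow(px), ncol(px)))
}

#' Bridge contour gaps and fill enclosed holes
#'
#' Applies morphological closing with a disc sized to bridge edge breaks of
#' at most `max_gap` pixels, then flood-fills the interior of closed
#' contours, turning egg outlines into solid blobs. Contours with breaks
#' wider than `max_gap` stay open and are not filled.
#'
#' @param edges A `binary_image` (e.g. from [canny_edges()]) or logical
#'   matrix.
#' @param max_gap Largest edge break, in pixels, that should be bridged;
#'   `>= 0` (0 = fill holes only).
#' @return A `binary_image` of solid filled blobs.
#' @export
fill_gaps_and_holes <- function(edges, max_gap = 2) {
  m <- as_mask(edges)
  if (max_gap < 0) stop("`max_gap` must be >= 0")
  if (max_gap > 0) {
    radius <- ceiling(max_gap / 2)
    brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
    m <- EBImage::closing(m * 1, brush) > 0.5
  }
  filled <- EBImage::fillHull(m * 1) > 0.5
  binary_image(matrix(filled, nrow(m), ncol(m)))
}
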