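# Connected-component labeling and per-region morphology statistics.

# 8-connectivity labeling built on EBImage::bwlabel (which is 4-connected):
# labels that touch diagonally are merged with a small union-find over the
# label adjacency pairs.
label_mask <- function(mask, connectivity = 8L) {
  lbl <- EBImage::bwlabel(mask * 1)
  lbl <- matrix(as.integer(round(lbl)), nrow(mask), ncol(mask))
  if (connectivity == 4L || max(lbl) < 2L) return(lbl)

  nr <- nrow(lbl); nc <- ncol(lbl)
  # diagonal neighbor pairs: down-right and down-left
  a1 <- lbl[-nr, -nc]; b1 <- lbl[-1, -1]
  a2 <- lbl[-nr, -1];  b2 <- lbl[-1, -nc]
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(pairs) == 0L) return(lbl)

  parent <- seq_len(max(lbl))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  remap <- match(root, sort(unique(root)))
  lbl[lbl > 0L] <- remap[lbl[lbl > 0L]]
  lbl
}

#' Label connected components and measure their morphology
#'
#' Partitions the foreground of a binary mask into connected regions and
#' returns one row of morphology descriptors per region: area, centroid,
#' bounding box, perimeter and eccentricity, plus mean source intensity when
#' the source image is supplied. These descriptors drive all downstream
#' shape filtering (worm size limits, elongation, egg templates).
#'
#' Coordinates are 1-based `(row, col)`; bounding boxes are inclusive.
#' Perimeter is counted as the number of foreground pixels with at least one
#' 4-connected background neighbor. Eccentricity comes from the central
#' second moments (0 for a disk or single pixel, near 1 for a line).
#'
#' @param mask A `binary_image` or logical matrix.
#' @param connectivity 8 (default) or 4.
#' @param intensity Optional `gray_image` or matrix from which per-region
#'   mean intensity is computed.
#' @return A data frame of class `worm_regions` with columns `label`,
#'   `area`, `centroid_r`, `centroid_c`, `min_row`, `min_col`, `max_row`,
#'   `max_col`, `perimeter`, `eccentricity` and (optionally)
#'   `mean_intensity`; the integer label matrix is attached as
#'   `attr(, "labels")`. Zero regions give a zero-row data frame.
#' @export
label_regions <- function(mask, connectivity = 8, intensity = NULL) {
  m <- as_mask(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8")
  lbl <- label_mask(m, connectivity)
  n <- max(lbl)

  empty <- data.frame(label = integer(), area = integer(),
                      centroid_r = numeric(), centroid_c = numeric(),
                      min_row = integer(), min_col = integer(),
                      max_row = integer(), max_col = integer(),
                      perimeter = integer(), eccentricity = numeric(),
                      semi_major = numeric(), semi_minor = numeric())
  if (n == 0L) {
    out <- empty
    if (!is.null(intensity)) out$mean_intensity <- numeric()
    attr(out, "labels") <- lbl
    class(out) <- c("worm_regions", "data.frame")
    return(out)
  }

  idx <- which(lbl > 0L)
  lab <- lbl[idx]
  nr <- nrow(m)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L

  area <- tabulate(lab, n)
  sr <- rowsum(rows, lab); sc <- rowsum(cols, lab)
  cr <- as.vector(sr) / area
  cc <- as.vector(sc) / area

  by_lab <- split(seq_along(lab), lab)
  min_row <- vapply(by_lab, function(i) min(rows[i]), numeric(1))
  max_row <- vapply(by_lab, function(i) max(rows[i]), numeric(1))
  min_col <- vapply(by_lab, function(i) min(cols[i]), numeric(1))
  max_col <- vapply(by_lab, function(i) max(cols[i]), numeric(1))

  # boundary pixels: any 4-neighbor outside the mask
  interior <- shift_mat(m, 1, 0, FALSE) & shift_mat(m, -1, 0, FALSE) &
    shift_mat(m, 0, 1, FALSE) & shift_mat(m, 0, -1, FALSE)
  border <- m & !interior
  per <- tabulate(lbl[which(border)], n)

  # central second moments -> eccentricity of the equivalent ellipse
  dr <- rows - cr[lab]; dc <- cols - cc[lab]
  mu20 <- as.vector(rowsum(dr * dr, lab)) / area
  mu02 <- as.vector(rowsum(dc * dc, lab)) / area
  mu11 <- as.vector(rowsum(dr * dc, lab)) / area
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- pmax(tr^2 / 4 - det, 0)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- tr / 2 - sqrt(disc)
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
  # moment-equivalent ellipse semi-axes (2*sd along principal directions)
  semi_major <- 2 * sqrt(pmax(l1, 0))
  semi_minor <- 2 * sqrt(pmax(l2, 0))

  out <- data.frame(label = seq_len(n), area = area,
                    centroid_r = cr, centroid_c = cc,
                    min_row = as.integer(min_row), min_col = as.integer(min_col),
                    max_row = as.integer(max_row), max_col = as.integer(max_col),
                    perimeter = per, eccentricity = ecc,
                    semi_major = semi_major, semi_minor = semi_minor)
  if (!is.null(intensity)) {
    px <- as_pixels(intensity)
    if (!all(dim(px) == dim(m))) stop("intensity image shape must match mask")
    out$mean_intensity <- as.vector(rowsum(px[idx], lab)) / area
  }
  attr(out, "labels") <- lbl
  class(out) <- c("worm_regions", "data.frame")
  out
}

#' @export
print.worm_regions <- function(x, ...) {
  cat(sprintf("<worm_regions> %d region(s), total area %d px\n",
              nrow(x), sum(x$area)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}

# Extract one region's mask, cropped to its bbox with `pad` background px.
crop_region <- function(labels, region_row, pad = 2L) {
  r1 <- max(region_row$min_row - pad, 1L)
  r2 <- min(region_row$max_row + pad, nrow(labels))
  c1 <- max(region_row$min_col - pad, 1L)
  c2 <- min(region_row$max_col + pad, ncol(labels))
  list(mask = labels[r1:r2, c1:c2, drop = FALSE] == region_row$label,
       offset = c(r1 - 1L, c1 - 1L))
}

bbox_intersects <- function(a, b) {
  a["min_row"] <= b["max_row"] && b["min_row"] <= a["max_row"] &&
    a["min_col"] <= b["max_col"] && b["min_col"] <= a["max_col"]
}
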