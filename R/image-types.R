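#' Grayscale plate image
#'
#' Container for an 8-bit grayscale image plus its spatial calibration.
#' All engines in the package consume and return these objects. Pixel values
#' are stored as a numeric matrix in `[0, 255]` indexed `[row, col]`
#' (1-based, row 1 at the top).
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`. Values are
#'   rounded to integers on construction.
#' @param scale Spatial calibration in micrometers per pixel. Dissecting
#'   scope rigs for plate-level worm imaging are typically around
#'   20 um/px, the default.
#' @return An object of class `gray_image` with elements `pixels`, `width`,
#'   `height` and `scale`.
#' @seealso [read_gray_image()], [adaptive_threshold()]
#' @export
gray_image <- function(pixels, scale = 20) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("`scale` must be a single positive number (um per pixel)")
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    stop("intensities must lie in [0, 255]")
  structure(
    list(pixels = px, width = ncol(px), height = nrow(px),
         scale = as.numeric(scale)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.3g um/px, intensity [%d, %d]\n",
              x$height, x$width, x$scale, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary mask over a grayscale image
#'
#' @param mask Logical matrix; `TRUE` marks foreground (object) pixels.
#' @param foreground Either `"dark"` (objects darker than background, the
#'   plate-imaging convention: worms and eggs on bright agar) or `"bright"`.
#' @return An object of class `binary_image` with elements `mask` and
#'   `foreground`.
#' @export
binary_image <- function(mask, foreground = c("dark", "bright")) {
  foreground <- match.arg(foreground)
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  if (anyNA(mask)) stop("mask must not contain NA")
  structure(list(mask = mask, foreground = foreground),
            class = "binary_image")
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image> %d x %d px, %d foreground px (%s objects)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$foreground))
  invisible(x)
}

# Coerce gray_image / matrix input to an intensity matrix.
as_pixels <- function(img) {
  if (inherits(img, "gray_image")) img$pixels
  else if (is.matrix(img) && is.numeric(img)) img
  else stop("expected a `gray_image` or a numeric matrix")
}

as_mask <- function(x) {
  if (inherits(x, "binary_image")) x$mask
  else if (is.matrix(x) && is.logical(x)) x
  else if (is.matrix(x) && is.numeric(x)) x != 0
  else stop("expected a `binary_image` or a logical matrix")
}

#' Read a grayscale image from PNG or TIFF
#'
#' Color inputs are converted to luminance (Rec. 601 weights). Multi-page
#' TIFFs are returned as a list of `gray_image`, one per page.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param scale Micrometers per pixel recorded on the returned image(s).
#' @return A `gray_image`, or a list of them for a multi-page TIFF.
#' @export
read_gray_image <- function(path, scale = 20) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    gray_image(luminance(arr) * 255, scale = scale)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    imgs <- lapply(pages, function(a) gray_image(luminance(a) * 255, scale))
    if (length(imgs) == 1L) imgs[[1L]] else imgs
  } else {
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  }
}

#' Write a grayscale image to PNG
#'
#' @param img A `gray_image` (or numeric matrix in `[0, 255]`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  px <- as_pixels(img)
  png::writePNG(px / 255, target = path)
  invisible(path)
}

luminance <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  nch <- dim(arr)[3]
  if (nch >= 3L)
    0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  else
    arr[, , 1]
}

# Shift a matrix by (dr, dc), padding with `fill`. Workhorse for the
# neighborhood operations (thinning, Canny, edge tests).
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}
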