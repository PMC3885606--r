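# Fixture builders and independent brute-force oracles used across tests.

# plain dark square on bright field
fix_square_image <- function(side = 60, sq = 20:29, bg = 200, fg = 40) {
  px <- matrix(bg, side, side)
  px[sq, sq] <- fg
  gray_image(px)
}

fix_disk_mask <- function(size, center, radius) {
  m <- matrix(FALSE, size[1], size[2])
  for (r in seq_len(size[1])) for (c in seq_len(size[2]))
    if ((r - center[1])^2 + (c - center[2])^2 <= radius^2) m[r, c] <- TRUE
  m
}

fix_ring_mask <- function(size, center, radius, break_at = NULL,
                          break_len = 0) {
  th <- seq(0, 2 * pi, length.out = 720)
  if (!is.null(break_at)) {
    arc <- break_len / radius
    keep <- !(th > break_at & th < break_at + arc)
    th <- th[keep]
  }
  m <- matrix(FALSE, size[1], size[2])
  r <- round(center[1] + radius * sin(th))
  c <- round(center[2] + radius * cos(th))
  m[cbind(r, c)] <- TRUE
  m
}

# thick straight capsule at an arbitrary angle, built independently of the
# simulator: pixels within `thickness/2` of the center segment (rounded
# ends, so the midline arc length is exactly `length_px`)
fix_bar_image <- function(length_px, thickness, angle, size = NULL,
                          bg = 220, fg = 30) {
  pad <- thickness + 6
  if (is.null(size)) {
    ext <- ceiling(length_px * max(abs(cos(angle)), abs(sin(angle)))) + 2 * pad
    size <- c(ext, ext)
  }
  ctr <- size / 2
  d <- c(sin(angle), cos(angle))
  px <- matrix(bg, size[1], size[2])
  for (r in seq_len(size[1])) for (c in seq_len(size[2])) {
    v <- c(r, c) - ctr
    along <- max(min(sum(v * d), length_px / 2), -length_px / 2)
    nearest <- ctr + along * d
    if (sqrt(sum((c(r, c) - nearest)^2)) <= thickness / 2) px[r, c] <- fg
  }
  gray_image(px)
}

# brute-force per-pixel local-mean threshold (oracle for the integral-image
# implementation); dark-object polarity
oracle_local_mean_threshold <- function(px, window, offset) {
  h <- (window - 1) / 2
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- max(1, r - h):min(nr, r + h)
    cs <- max(1, c - h):min(nc, c + h)
    out[r, c] <- px[r, c] < mean(px[rs, cs]) * (1 - offset)
  }
  out
}

# brute-force union-find connected-component labeling (oracle)
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(list(n = 0, sizes = integer()))
  parent <- seq_along(idx)
  pos <- match(seq_len(nr * nc), idx)   # linear index -> candidate id
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  offs <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
  else rbind(c(-1, 0), c(0, -1))
  for (k in seq_along(idx)) {
    i <- idx[k]
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    for (o in seq_len(nrow(offs))) {
      rr <- r + offs[o, 1]; cc <- c + offs[o, 2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      j <- (cc - 1) * nr + rr
      if (!mask[j]) next
      a <- find(k); b <- find(pos[j])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  list(n = length(unique(roots)), sizes = sort(as.integer(table(roots))))
}
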