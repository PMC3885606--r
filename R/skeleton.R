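# Skeletonization (Zhang-Suen thinning) and skeleton-curve measurement.

# One Zhang-Suen pass over a logical matrix. Returns the thinned matrix.
# Neighborhood labels follow the classic scheme: P2=N, P3=NE, ... P9=NW.
zhang_suen <- function(m) {
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift_mat(m, 1, 0, FALSE)   # value of northern neighbor at each px
      p3 <- shift_mat(m, 1, -1, FALSE)
      p4 <- shift_mat(m, 0, -1, FALSE)
      p5 <- shift_mat(m, -1, -1, FALSE)
      p6 <- shift_mat(m, -1, 0, FALSE)
      p7 <- shift_mat(m, -1, 1, FALSE)
      p8 <- shift_mat(m, 0, 1, FALSE)
      p9 <- shift_mat(m, 1, 1, FALSE)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  condense_skeleton(m)
}

# Zhang-Suen output is not strictly one pixel wide on diagonal staircases.
# Remove redundant pixels: any non-endpoint that is 8-simple (Yokoi
# connectivity number 1 for 8-connected foreground) can be deleted without
# changing connectivity. Deletions run in four checkerboard phases
# (same-phase pixels are never 8-adjacent) so parallel removal cannot
# disconnect the curve.
condense_skeleton <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  phase_r <- matrix(seq_len(nr) %% 2L, nr, nc)
  phase_c <- matrix(rep(seq_len(nc) %% 2L, each = nr), nr, nc)
  repeat {
    changed <- FALSE
    for (ph in 0:3) {
      n_  <- shift_mat(m, 1, 0, FALSE);  ne <- shift_mat(m, 1, -1, FALSE)
      e_  <- shift_mat(m, 0, -1, FALSE); se <- shift_mat(m, -1, -1, FALSE)
      s_  <- shift_mat(m, -1, 0, FALSE); sw <- shift_mat(m, -1, 1, FALSE)
      w_  <- shift_mat(m, 0, 1, FALSE);  nw <- shift_mat(m, 1, 1, FALSE)
      b <- n_ + ne + e_ + se + s_ + sw + w_ + nw
      # Yokoi number for 8-connected foreground over x0..x7 = E,NE,N,NW,W,SW,S,SE
      x <- list(e_, ne, n_, nw, w_, sw, s_, se)
      cn <- 0
      for (k in c(1L, 3L, 5L, 7L)) {
        xk <- !x[[k]]; xk1 <- !x[[(k %% 8L) + 1L]]; xk2 <- !x[[((k + 1L) %% 8L) + 1L]]
        cn <- cn + (xk - (xk & xk1 & xk2))
      }
      cond <- m & b >= 2 & b <= 6 & cn == 1 &
        phase_r == (ph %/% 2L) & phase_c == (ph %% 2L)
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

neighbor_count <- function(m) {
  shift_mat(m, 1, 0, FALSE) + shift_mat(m, -1, 0, FALSE) +
    shift_mat(m, 0, 1, FALSE) + shift_mat(m, 0, -1, FALSE) +
    shift_mat(m, 1, 1, FALSE) + shift_mat(m, 1, -1, FALSE) +
    shift_mat(m, -1, 1, FALSE) + shift_mat(m, -1, -1, FALSE)
}

# Remove spur branches of at most `max_len` pixels: walk inward from each
# endpoint; if a branch point is reached within max_len steps, delete the
# walked spur. Repeats until stable.
prune_spurs <- function(m, max_len) {
  if (max_len <= 0) return(m)
  repeat {
    ncnt <- neighbor_count(m)
    ends <- which(m & ncnt == 1)
    branch_exists <- any(m & ncnt >= 3)
    if (!length(ends) || !branch_exists) return(m)
    removed_any <- FALSE
    nr <- nrow(m)
    for (e in ends) {
      walk <- integer(0)
      cur <- e; prev <- -1L
      ok <- FALSE
      for (step in seq_len(max_len)) {
        walk <- c(walk, cur)
        r <- ((cur - 1L) %% nr) + 1L; c <- ((cur - 1L) %/% nr) + 1L
        nb <- neighbors_of(m, r, c)
        nb <- setdiff(nb, c(prev, walk))
        if (!length(nb)) break
        nxt <- nb[1]
        nr2 <- ((nxt - 1L) %% nr) + 1L; nc2 <- ((nxt - 1L) %/% nr) + 1L
        if (neighbor_count_at(m, nr2, nc2) >= 3) { ok <- TRUE; break }
        prev <- cur; cur <- nxt
      }
      if (ok && length(walk)) { m[walk] <- FALSE; removed_any <- TRUE }
    }
    if (!removed_any) return(m)
  }
}

neighbors_of <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  rs <- max(1, r - 1):min(nr, r + 1)
  cs <- max(1, c - 1):min(nc, c + 1)
  out <- integer(0)
  for (cc in cs) for (rr in rs) {
    if ((rr != r || cc != c) && m[rr, cc]) out <- c(out, (cc - 1L) * nr + rr)
  }
  out
}

neighbor_count_at <- function(m, r, c) {
  length(neighbors_of(m, r, c))
}

#' Skeletonize a single-object mask
#'
#' Thins a connected foreground component to a one-pixel-wide 8-connected
#' medial curve (Zhang-Suen thinning) and characterizes it: number of
#' branch points (skeleton pixels with three or more skeleton neighbors),
#' endpoints (exactly one neighbor), and, when the skeleton is a single
#' branch-free open curve, the ordered pixel path from one endpoint to the
#' other. A worm silhouette yields a branch-free curve with two endpoints;
#' protrusions, overlaps with eggs or debris, and compact blobs yield
#' branches or degenerate skeletons and are flagged by downstream filters.
#'
#' @param mask A `binary_image` or logical matrix holding one connected
#'   component.
#' @param prune Spur-pruning length in pixels: side branches of at most this
#'   length emanating from branch points are removed before analysis
#'   (boundary roughness of a thick body often leaves 1-3 px spurs).
#'   Default 0 (no pruning).
#' @return An object of class `worm_skeleton`: list with `pixels` (n x 2
#'   matrix of all skeleton `(row, col)`), `path` (ordered n x 2 matrix when
#'   traceable, otherwise the pixels in raster order), `traceable` (logical),
#'   `branch_count`, and `endpoints` (k x 2 matrix).
#' @export
skeletonize <- function(mask, prune = 0) {
  m <- as_mask(mask)
  if (!any(m)) stop("cannot skeletonize an empty mask")
  sk <- zhang_suen(m)
  if (!any(sk)) stop("mask eroded to an empty skeleton")
  sk <- prune_spurs(sk, prune)
  analyze_skeleton(sk)
}

# Branch/endpoint analysis and path tracing of a thinned skeleton matrix.
analyze_skeleton <- function(sk) {
  ncnt <- neighbor_count(sk)
  nrr <- nrow(sk)
  idx <- which(sk)
  pix <- cbind(row = ((idx - 1L) %% nrr) + 1L,
               col = ((idx - 1L) %/% nrr) + 1L)
  end_idx <- which(sk & ncnt == 1)
  endpoints <- cbind(row = ((end_idx - 1L) %% nrr) + 1L,
                     col = ((end_idx - 1L) %/% nrr) + 1L)
  branch_count <- sum(sk & ncnt >= 3)

  traceable <- branch_count == 0L &&
    (nrow(pix) == 1L || nrow(endpoints) == 2L)
  path <- pix
  if (traceable && nrow(pix) > 1L) {
    path <- trace_path(sk, end_idx[1], nrow(pix))
  }
  structure(list(pixels = pix, path = path, traceable = traceable,
                 branch_count = as.integer(branch_count),
                 endpoints = endpoints),
            class = "worm_skeleton")
}

# Walk a branch-free skeleton from `start` (linear index), visiting every
# pixel once. Returns an ordered (row, col) matrix.
trace_path <- function(sk, start, n_pix) {
  nr <- nrow(sk)
  visited <- matrix(FALSE, nr, ncol(sk))
  path <- matrix(0L, n_pix, 2L)
  cur <- start
  for (k in seq_len(n_pix)) {
    r <- ((cur - 1L) %% nr) + 1L; c <- ((cur - 1L) %/% nr) + 1L
    path[k, ] <- c(r, c)
    visited[cur] <- TRUE
    if (k == n_pix) break
    nb <- neighbors_of(sk, r, c)
    nb <- nb[!visited[nb]]
    if (!length(nb)) { path <- path[seq_len(k), , drop = FALSE]; break }
    # prefer 4-connected continuation to avoid cutting corners
    if (length(nb) > 1L) {
      rr <- ((nb - 1L) %% nr) + 1L; cc <- ((nb - 1L) %/% nr) + 1L
      d <- abs(rr - r) + abs(cc - c)
      nb <- nb[order(d)]
    }
    cur <- nb[1]
  }
  colnames(path) <- c("row", "col")
  path
}

#' @export
print.worm_skeleton <- function(x, ...) {
  cat(sprintf(
    "<worm_skeleton> %d px, %d branch point(s), %d endpoint(s)%s\n",
    nrow(x$pixels), x$branch_count, nrow(x$endpoints),
    if (x$traceable) ", traceable" else ""))
  invisible(x)
}

#' Skeleton-curve length by pixel tracing
#'
#' Measures a branch-free skeleton by walking the curve pixel by pixel and
#' summing step distances: 1 for a horizontal or vertical move, sqrt(2) for
#' a diagonal move.
#'
#' @param s A `worm_skeleton` with `branch_count == 0` and at least 2
#'   pixels, or an ordered n x 2 `(row, col)` path matrix whose consecutive
#'   pixels are 8-connected.
#' @return Length in pixels (numeric scalar).
#' @examples
#' bar <- matrix(FALSE, 5, 101); bar[3, ] <- TRUE
#' skeleton_length(skeletonize(bar))  # 100
#' @export
skeleton_length <- function(s) {
  if (inherits(s, "worm_skeleton")) {
    if (s$branch_count > 0)
      stop("skeleton has branch points; length is defined for branch-free curves")
    if (!s$traceable || nrow(s$path) < 2)
      stop("skeleton has fewer than 2 pixels or no traceable path")
    path <- s$path
  } else if (is.matrix(s) && ncol(s) == 2 && nrow(s) >= 2) {
    path <- s
  } else {
    stop("expected a `worm_skeleton` or an n x 2 path matrix")
  }
  st <- diff(path)
  if (any(abs(st) > 1))
    stop("consecutive path pixels must be 8-connected")
  diag_step <- st[, 1] != 0 & st[, 2] != 0
  sum(ifelse(diag_step, sqrt(2), 1))
}

# Euclidean polyline length of an n x 2 coordinate matrix.
polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}
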