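# Batch orchestration: tile assembly, batch engine runs, report files and
# file-based manual correction.

#' Plate tile layout
#'
#' @param rows,cols Tile grid dimensions.
#' @param tile_size `(height, width)` of each tile, px.
#' @param overlap Overlap between adjacent tiles, px (cropped on assembly).
#' @param well_id Optional well label carried into reports.
#' @return A `plate_layout` list.
#' @export
plate_layout <- function(rows, cols, tile_size = c(480, 640), overlap = 0,
                         well_id = NA_character_) {
  stopifnot(rows >= 1, cols >= 1, overlap >= 0,
            overlap < min(tile_size))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 tile_size = as.integer(tile_size),
                 overlap = as.integer(overlap), well_id = well_id),
            class = "plate_layout")
}

#' Assemble scanned tiles into one well mosaic
#'
#' Tiles are placed row-major; the stated overlap is cropped so the mosaic
#' measures `rows*h - (rows-1)*overlap` by `cols*w - (cols-1)*overlap`
#' (e.g. the standard 3x4 grid of 640x480 tiles gives 1440x2560).
#'
#' @param tiles List of `gray_image`/matrices in row-major order, or a list
#'   of rows each holding a list of tiles.
#' @param layout A [plate_layout()].
#' @return A `gray_image` mosaic.
#' @export
assemble_tiles <- function(tiles, layout) {
  stopifnot(inherits(layout, "plate_layout"))
  if (length(tiles) && is.list(tiles[[1]]) &&
      !inherits(tiles[[1]], "gray_image"))
    tiles <- do.call(c, tiles)
  if (length(tiles) != layout$rows * layout$cols)
    stop(sprintf("expected %d tiles (%d x %d), got %d",
                 layout$rows * layout$cols, layout$rows, layout$cols,
                 length(tiles)))
  h <- layout$tile_size[1]; w <- layout$tile_size[2]; ov <- layout$overlap
  scale <- NA_real_
  out <- matrix(0, layout$rows * h - (layout$rows - 1) * ov,
                layout$cols * w - (layout$cols - 1) * ov)
  for (i in seq_len(layout$rows)) {
    for (j in seq_len(layout$cols)) {
      k <- (i - 1) * layout$cols + j
      tile <- tiles[[k]]
      if (is.null(tile))
        stop(sprintf("missing tile at grid position (%d, %d)", i, j))
      if (inherits(tile, "gray_image")) scale <- tile$scale
      px <- as_pixels(tile)
      if (!all(dim(px) == c(h, w)))
        stop(sprintf("tile (%d, %d) is %dx%d, expected %dx%d",
                     i, j, nrow(px), ncol(px), h, w))
      r0 <- (i - 1) * (h - ov); c0 <- (j - 1) * (w - ov)
      out[r0 + seq_len(h), c0 + seq_len(w)] <- px
    }
  }
  gray_image(out, scale = if (is.na(scale)) 20 else scale)
}

#' Read a run configuration file
#'
#' YAML file with global `scale`, `fps`, `seed` and per-engine parameter
#' blocks (`lifespan`, `locomotion`, `length`, `egg`); every block is
#' validated through its engine's parameter constructor.
#'
#' @param path YAML file path.
#' @return A `run_config` list with validated parameter objects and the
#'   file's md5 `config_hash`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  scale <- raw$scale %||% 20
  fps <- raw$fps %||% 7
  build <- function(ctor, block, extra = list()) {
    do.call(ctor, utils::modifyList(extra, as.list(block %||% list())))
  }
  structure(list(
    scale = scale, fps = fps, seed = raw$seed %||% 1L,
    lifespan = build(lifespan_params, raw$lifespan),
    locomotion = build(tracker_params, raw$locomotion,
                       list(fps = fps, scale = scale)),
    length = build(length_params, raw$length, list(scale = scale)),
    egg = build(egg_params, raw$egg),
    config_hash = unname(tools::md5sum(path))),
    class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

report_header <- function(con, config_hash = NA_character_) {
  writeLines(c(sprintf("# generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("# config_hash: %s", config_hash)), con)
}

write_report <- function(df, path, config_hash = NA_character_) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  report_header(con, config_hash)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Batch-process a set of inputs through one engine
#'
#' Runs every input through the chosen engine, collecting one result row
#' per input; unreadable or failing inputs are logged, skipped, and
#' reflected in the exit status. Outputs are ordered as given.
#'
#' @param inputs For `length` and `egg`: character vector of image paths.
#'   For `lifespan`: a two-column data frame (`img1`, `img2`) or character
#'   vector of `"img1,img2"` pairs. For `locomotion`: character vector of
#'   frame directories.
#' @param engine One of `"lifespan"`, `"locomotion"`, `"length"`, `"egg"`.
#' @param cfg A `run_config` (see [read_run_config()]) or NULL for
#'   defaults.
#' @param out_file Optional TSV report path.
#' @return Data frame of class `batch_result` with one row per input and a
#'   `status` column; `attr(, "exit_status")` is 0 only if every input
#'   succeeded.
#' @export
batch_process <- function(inputs, engine = c("lifespan", "locomotion",
                                             "length", "egg"),
                          cfg = NULL, out_file = NULL) {
  engine <- match.arg(engine)
  if (engine == "lifespan" && is.character(inputs)) {
    parts <- strsplit(inputs, ",")
    inputs <- data.frame(img1 = vapply(parts, `[`, "", 1),
                         img2 = vapply(parts, `[`, "", 2))
  }
  n <- if (is.data.frame(inputs)) nrow(inputs) else length(inputs)
  if (n == 0) stop("no inputs to process")
  if (is.null(cfg))
    cfg <- list(scale = 20, fps = 7, lifespan = lifespan_params(),
                locomotion = tracker_params(), length = length_params(),
                egg = egg_params(), config_hash = NA_character_)

  one <- function(i) {
    if (engine == "lifespan") {
      a <- read_gray_image(inputs$img1[i], scale = cfg$scale)
      b <- read_gray_image(inputs$img2[i], scale = cfg$scale)
      r <- count_moving_worms(a, b, cfg$lifespan)
      data.frame(input = inputs$img1[i], n_moving = r$n_moving,
                 n_candidates = nrow(r$rois))
    } else if (engine == "locomotion") {
      r <- track_video(inputs[i], cfg$locomotion)
      data.frame(input = inputs[i], n_tracks = r$summary$n_tracks,
                 mean_velocity_um_s = r$summary$mean)
    } else if (engine == "length") {
      img <- read_gray_image(inputs[i], scale = cfg$scale)
      m <- measure_worms(img, cfg$length)
      v <- m[m$valid, , drop = FALSE]
      data.frame(input = inputs[i], n_valid = nrow(v),
                 mean_length_um = if (nrow(v)) mean(v$length_um) else NA_real_)
    } else {
      img <- read_gray_image(inputs[i], scale = cfg$egg$scale %||% cfg$scale)
      r <- count_eggs(img, cfg$egg)
      data.frame(input = inputs[i], n_eggs = r$n_eggs)
    }
  }

  rows <- vector("list", n)
  status <- character(n)
  for (i in seq_len(n)) {
    res <- tryCatch(one(i), error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- conditionMessage(res)
      message(sprintf("[batch %s] input %d failed: %s", engine, i,
                      conditionMessage(res)))
      id <- if (is.data.frame(inputs)) inputs$img1[i] else inputs[i]
      rows[[i]] <- data.frame(input = id)
    } else {
      status[i] <- "ok"
      rows[[i]] <- res
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    # align columns across success/failure rows
    all_cols <- unique(unlist(lapply(rows, names)))
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA
    r[all_cols]
  }))
  out$status <- status
  attr(out, "exit_status") <- if (all(status == "ok")) 0L else 1L
  class(out) <- c("batch_result", "data.frame")
  if (!is.null(out_file)) write_report(out, out_file, cfg$config_hash)
  out
}

#' Apply a manual-correction file to a results report
#'
#' File-based counterpart of interactive result inspection: a corrections
#' TSV with columns `action` (`delete`, `edit`, `add`), `id`, and for edits
#' `field` and `value`. The whole correction file is validated first; any
#' correction referencing an unknown record id rejects the file atomically
#' and leaves the results untouched. The amended report carries an `audit`
#' column describing what was changed.
#'
#' @param results_file TSV report with an `id` column.
#' @param corrections_file Corrections TSV (may have zero rows).
#' @param out_file Amended report path (default: overwrite `results_file`).
#' @return The amended data frame, invisibly.
#' @export
apply_corrections <- function(results_file, corrections_file,
                              out_file = results_file) {
  res <- read_report(results_file)
  if (!"id" %in% names(res)) stop("results file has no `id` column")
  cor <- read_report(corrections_file)
  if (!"audit" %in% names(res)) res$audit <- ""

  if (nrow(cor)) {
    needed <- c("action", "id")
    if (!all(needed %in% names(cor)))
      stop("corrections file must have `action` and `id` columns")
    refs <- cor$id[cor$action %in% c("delete", "edit")]
    unknown <- setdiff(refs, res$id)
    if (length(unknown))
      stop("corrections rejected: unknown record id(s) ",
           paste(unknown, collapse = ", "), " (no changes applied)")
    for (i in seq_len(nrow(cor))) {
      act <- cor$action[i]
      if (act == "delete") {
        res <- res[res$id != cor$id[i], , drop = FALSE]
      } else if (act == "edit") {
        j <- which(res$id == cor$id[i])
        fld <- cor$field[i]
        if (!fld %in% names(res)) stop("unknown field in edit: ", fld)
        res[j, fld] <- utils::type.convert(as.character(cor$value[i]),
                                           as.is = TRUE)
        res$audit[j] <- paste0(res$audit[j], sprintf("edit:%s;", fld))
      } else if (act == "add") {
        new <- res[0, , drop = FALSE][1, ]
        new$id <- cor$id[i]
        if (!is.na(cor$field[i]) && cor$field[i] %in% names(res))
          new[[cor$field[i]]] <- utils::type.convert(
            as.character(cor$value[i]), as.is = TRUE)
        new$audit <- "added;"
        res <- rbind(res, new)
      } else {
        stop("unknown correction action: ", act)
      }
    }
    deleted <- cor$id[cor$action == "delete"]
    if (length(deleted))
      attr(res, "deleted") <- deleted
  }
  write_report(res, out_file)
  invisible(res)
}

#' Write an overlay image marking detections
#'
#' Renders the grayscale image as RGB with region bounding boxes tinted:
#' green for accepted/moving detections, red for rejected/still ones.
#'
#' @param img A `gray_image`.
#' @param regions A `worm_regions` (or compatible) data frame.
#' @param accepted Logical vector, one per region.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(img, regions, accepted, path) {
  px <- as_pixels(img) / 255
  rgb <- array(px, c(nrow(px), ncol(px), 3))
  for (i in seq_len(nrow(regions))) {
    rs <- regions$min_row[i]:regions$max_row[i]
    cs <- regions$min_col[i]:regions$max_col[i]
    ch <- if (accepted[i]) 2 else 1      # green vs red channel
    rgb[rs, c(cs[1], cs[length(cs)]), ch] <- 1
    rgb[c(rs[1], rs[length(rs)]), cs, ch] <- 1
  }
  png::writePNG(rgb, target = path)
  invisible(path)
}
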