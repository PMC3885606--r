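test_that("tile assembly reproduces the standard well mosaic size", {
  lay <- plate_layout(3, 4, tile_size = c(480, 640), overlap = 0)
  tiles <- lapply(1:12, function(i) gray_image(matrix(i * 10, 480, 640)))
  mosaic <- assemble_tiles(tiles, lay)
  expect_identical(dim(mosaic$pixels), c(1440L, 2560L))
  # row-major placement
  expect_equal(mosaic$pixels[1, 1], 10)
  expect_equal(mosaic$pixels[1440, 2560], 120)
})

test_that("single-tile assembly is the identity and overlap crops", {
  t1 <- gray_image(matrix(77, 100, 120))
  lay <- plate_layout(1, 1, tile_size = c(100, 120))
  expect_identical(assemble_tiles(list(t1), lay)$pixels, t1$pixels)

  lay2 <- plate_layout(2, 2, tile_size = c(100, 120), overlap = 20)
  tiles <- lapply(1:4, function(i) gray_image(matrix(i, 100, 120)))
  m <- assemble_tiles(tiles, lay2)
  expect_identical(dim(m$pixels), c(180L, 220L))
})

test_that("missing and mis-sized tiles are rejected with their position", {
  lay <- plate_layout(1, 2, tile_size = c(50, 50))
  good <- gray_image(matrix(1, 50, 50))
  expect_error(assemble_tiles(list(good, NULL), lay), "\\(1, 2\\)")
  bad <- gray_image(matrix(1, 50, 60))
  expect_error(assemble_tiles(list(good, bad), lay), "expected 50x50")
})

test_that("batch processing reports per-input status and exit code", {
  dir <- withr::local_tempdir()
  paths <- character(3)
  for (i in 1:2) {
    p <- render_egg_plate(10 + 5 * i, seed = 70 + i, canvas = c(240, 320))
    paths[i] <- file.path(dir, sprintf("plate%d.png", i))
    write_gray_image(p$image, paths[i])
  }
  paths[3] <- file.path(dir, "missing.png")
  out_file <- file.path(dir, "report.tsv")
  cfg5 <- list(scale = 5, fps = 7, egg = egg_params(),
               config_hash = NA_character_)
  res <- batch_process(paths, "egg", cfg = cfg5, out_file = out_file)
  expect_identical(res$status[1:2], c("ok", "ok"))
  expect_false(res$status[3] == "ok")
  expect_identical(attr(res, "exit_status"), 1L)
  expect_true(file.exists(out_file))

  ok <- batch_process(paths[1:2], "egg", cfg = cfg5)
  expect_identical(attr(ok, "exit_status"), 0L)
  expect_error(batch_process(character(0), "egg"), "no inputs")
})

test_that("corrections apply atomically with an audit trail", {
  dir <- withr::local_tempdir()
  res_file <- file.path(dir, "lengths.tsv")
  df <- data.frame(id = 1:10, length_um = seq(900, 1800, by = 100))
  wormvision:::write_report(df, res_file)

  # delete one record
  cor_file <- file.path(dir, "fix.tsv")
  wormvision:::write_report(
    data.frame(action = "delete", id = 3, field = NA, value = NA), cor_file)
  out <- apply_corrections(res_file, cor_file,
                           out_file = file.path(dir, "amended.tsv"))
  expect_identical(nrow(out), 9L)
  expect_false(3 %in% out$id)

  # empty corrections leave the data unchanged
  wormvision:::write_report(
    data.frame(action = character(), id = integer(),
               field = character(), value = character()),
    cor_file)
  out2 <- apply_corrections(res_file, cor_file,
                            out_file = file.path(dir, "amended2.tsv"))
  expect_equal(out2$id, df$id)
  expect_equal(out2$length_um, df$length_um)

  # unknown id rejects the whole file and leaves the target untouched
  wormvision:::write_report(
    data.frame(action = c("edit", "delete"), id = c(2, 99),
               field = c("length_um", NA), value = c("1234", NA)), cor_file)
  before <- wormvision:::read_report(res_file)
  expect_error(apply_corrections(res_file, cor_file), "unknown record id")
  expect_identical(wormvision:::read_report(res_file), before)
})

test_that("run configs validate engine blocks and hash the file", {
  dir <- withr::local_tempdir()
  cfg_file <- file.path(dir, "run.yaml")
  writeLines(c("scale: 10", "fps: 14",
               "lifespan:", "  min_worm_area: 60",
               "egg:", "  min_occurrences: 4"), cfg_file)
  cfg <- read_run_config(cfg_file)
  expect_equal(cfg$scale, 10)
  expect_equal(cfg$lifespan$min_worm_area, 60)
  expect_equal(cfg$locomotion$fps, 14)
  expect_equal(cfg$egg$min_occurrences, 4)
  expect_match(cfg$config_hash, "^[0-9a-f]{32}$")

  writeLines(c("lifespan:", "  min_worm_area: -5"), cfg_file)
  expect_error(read_run_config(cfg_file))
})

test_that("re-running an engine on identical input gives identical reports", {
  dir <- withr::local_tempdir()
  p <- render_egg_plate(18, cluster_fraction = 0.2, seed = 81,
                        canvas = c(240, 320))
  img_path <- file.path(dir, "plate.png")
  write_gray_image(p$image, img_path)
  cfg5 <- list(scale = 5, fps = 7, egg = egg_params(),
               config_hash = NA_character_)
  r1 <- batch_process(img_path, "egg", cfg = cfg5)
  r2 <- batch_process(img_path, "egg", cfg = cfg5)
  expect_identical(r1$n_eggs, r2$n_eggs)
})
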