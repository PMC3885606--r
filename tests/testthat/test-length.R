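small_params <- function() {
  length_params(min_area = 200, max_area = 20000, fatness_range = c(2.5, 12),
                min_bbox_side = 20)
}

test_that("an empty image yields no measurements", {
  m <- measure_worms(gray_image(matrix(210, 200, 200)), small_params())
  expect_identical(nrow(m), 0L)
})

test_that("a straight bar is measured to its known length", {
  img <- fix_bar_image(150, 7, angle = 0.3, size = c(260, 260))
  m <- measure_worms(img, small_params())
  expect_identical(sum(m$valid), 1L)
  expect_lt(abs(m$length_px[m$valid] - 150) / 150, 0.03)
  expect_equal(m$length_um[m$valid], m$length_px[m$valid] * 20)
})

test_that("the same worm measured at several orientations agrees within 3 percent", {
  lens <- vapply(c(0, pi / 6, pi / 4, pi / 2), function(a) {
    img <- fix_bar_image(150, 7, angle = a, size = c(280, 280))
    m <- measure_worms(img, small_params())
    m$length_px[m$valid][1]
  }, numeric(1))
  expect_lt((max(lens) - min(lens)) / min(lens), 0.03)
})

test_that("doubling the calibration doubles micrometers but not pixels", {
  img <- fix_bar_image(120, 7, angle = 0.8, size = c(240, 240))
  m20 <- measure_worms(gray_image(img$pixels, scale = 20), small_params())
  m40 <- measure_worms(gray_image(img$pixels, scale = 40), small_params())
  expect_equal(m20$length_px, m40$length_px)
  expect_equal(m40$length_um, 2 * m20$length_um)
})

test_that("a worm overlapping an egg is rejected as branched", {
  img <- fix_bar_image(150, 7, angle = 0.25, size = c(260, 260))
  px <- img$pixels
  # a side blob fused to the body induces a skeleton branch
  ctr <- which(px < 100, arr.ind = TRUE)
  mid <- ctr[which.min(abs(ctr[, 1] - mean(ctr[, 1]))), ]
  px[fix_disk_mask(dim(px), mid + c(7, 0), 6)] <- 30
  m <- measure_worms(gray_image(px), small_params())
  expect_identical(sum(m$valid), 0L)
  expect_true("branched" %in% m$reject_reason)
})

test_that("a round blob is rejected as too fat", {
  px <- matrix(220, 200, 200)
  px[fix_disk_mask(c(200, 200), c(100, 100), 25)] <- 30
  m <- measure_worms(gray_image(px), small_params())
  expect_identical(sum(m$valid), 0L)
  expect_identical(m$reject_reason, "too_fat")
})

test_that("size filters annotate rejects without dropping them", {
  px <- matrix(220, 300, 300)
  px[100:101, 100:110] <- 30                         # tiny fleck
  px[fix_disk_mask(c(300, 300), c(200, 200), 45)] <- 30  # huge mass
  m <- measure_worms(gray_image(px),
                     length_params(min_area = 200, max_area = 3000,
                                   fatness_range = c(2.5, 12),
                                   min_bbox_side = 20))
  expect_identical(nrow(m), 2L)
  expect_setequal(m$reject_reason, c("too_small", "too_large"))
})

test_that("simulated worms of known arc length are measured accurately", {
  p <- render_length_plate(6, length_range = c(600, 1200), seed = 44,
                           canvas = c(1600, 1600))
  lp <- length_params(min_area = 1000, max_area = 40000,
                      fatness_range = c(4, 16), min_bbox_side = 30)
  m <- measure_worms(p$image, lp)
  v <- m[m$valid, ]
  expect_identical(nrow(v), 6L)
  errs <- vapply(seq_len(nrow(v)), function(i) {
    j <- which.min((p$truth$center_r - v$centroid_r[i])^2 +
                     (p$truth$center_c - v$centroid_c[i])^2)
    abs(v$length_px[i] - p$truth$arc_length_px[j]) / p$truth$arc_length_px[j]
  }, numeric(1))
  expect_lt(mean(errs), 0.013)
})
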