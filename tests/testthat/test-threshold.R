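test_that("uniform image yields an all-background mask", {
  img <- gray_image(matrix(128, 50, 50))
  m <- adaptive_threshold(img, window = 15)
  expect_false(any(m$mask))
})

test_that("a dark square on a bright field is segmented exactly", {
  img <- fix_square_image()
  m <- adaptive_threshold(img, window = 31, offset_fraction = 0.15)
  expect_identical(sum(m$mask), 100L)
  expect_true(all(m$mask[20:29, 20:29]))
  # must agree with the brute-force per-pixel oracle
  oracle <- oracle_local_mean_threshold(img$pixels, 31, 0.15)
  expect_identical(m$mask, oracle)
})

test_that("integral-image thresholding matches the per-pixel oracle on noisy images", {
  set.seed(71)
  for (k in 1:3) {
    px <- matrix(round(runif(40 * 45, 30, 220)), 40, 45)
    img <- gray_image(px)
    m <- adaptive_threshold(img, window = 11, offset_fraction = 0.1)
    expect_identical(m$mask, oracle_local_mean_threshold(px, 11, 0.1))
  }
})

test_that("an illumination ramp without objects stays almost empty", {
  ramp <- matrix(rep(seq(60, 220, length.out = 640), each = 480), 480, 640)
  m <- adaptive_threshold(gray_image(ramp), window = 31,
                          offset_fraction = 0.15)
  expect_lt(mean(m$mask), 0.01)
})

test_that("raising the offset fraction never adds foreground", {
  set.seed(72)
  px <- matrix(round(runif(60 * 60, 20, 230)), 60, 60)
  img <- gray_image(px)
  prev <- adaptive_threshold(img, window = 15, offset_fraction = 0)$mask
  for (off in c(0.05, 0.15, 0.3, 0.6)) {
    cur <- adaptive_threshold(img, window = 15, offset_fraction = off)$mask
    expect_true(all(prev | !cur))   # cur subset of prev
    prev <- cur
  }
})

test_that("bright-object polarity segments difference-style images", {
  px <- matrix(0, 50, 50); px[10:19, 10:19] <- 180
  m <- adaptive_threshold(gray_image(px), window = 21, dark_objects = FALSE)
  expect_identical(unname(which(m$mask, arr.ind = TRUE)[1, ] >= 10), c(TRUE, TRUE))
  expect_identical(sum(m$mask), 100L)
})

test_that("invalid windows and offsets are rejected", {
  img <- gray_image(matrix(100, 20, 20))
  expect_error(adaptive_threshold(img, window = 10), "odd")
  expect_error(adaptive_threshold(img, window = 31), "exceeds")
  expect_error(adaptive_threshold(img, window = 11, offset_fraction = 1),
               "offset")
})
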