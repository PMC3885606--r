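test_that("identical images contain no moving worms", {
  img <- fix_square_image()
  r <- count_moving_worms(img, img, lifespan_params(min_worm_area = 10))
  expect_identical(r$n_moving, 0L)
})

test_that("image shape mismatches are rejected", {
  a <- gray_image(matrix(100, 20, 20))
  b <- gray_image(matrix(100, 20, 30))
  expect_error(count_moving_worms(a, b), "dimensions")
})

test_that("simulated pairs are counted and flagged correctly", {
  p <- render_lifespan_pair(7, 7, seed = 21, canvas = c(700, 1100))
  r <- count_moving_worms(p$img1, p$img2)
  expect_identical(r$n_moving, 7L)
  expect_identical(sum(r$moving_flags), 7L)
  expect_identical(sum(!r$moving_flags), 7L)   # the still worms, unflagged
})

test_that("movers merged with large debris are recovered from the difference image", {
  blob <- function(m, r0, c0, rad, lev) {
    m[fix_disk_mask(dim(m), c(r0, c0), rad)] <- lev; m
  }
  px1 <- blob(matrix(220, 240, 240), 100, 100, 35, 20)
  px1[98:100, 130:169] <- 30
  px2 <- blob(matrix(220, 240, 240), 100, 100, 35, 20)
  px2[108:110, 130:169] <- 30
  r <- count_moving_worms(gray_image(px1), gray_image(px2))
  expect_identical(nrow(r$rois), 0L)            # merged blob fails size
  expect_identical(nrow(r$extra_movers), 1L)    # recovered from difference
  expect_identical(r$n_moving, 1L)
})

test_that("counting is symmetric in the image order for in-frame pairs", {
  for (s in c(31, 32)) {
    p <- render_lifespan_pair(5, 4, seed = s, canvas = c(600, 900))
    a <- count_moving_worms(p$img1, p$img2)$n_moving
    b <- count_moving_worms(p$img2, p$img1)$n_moving
    expect_identical(a, b)
  }
})

test_that("the step-wise decrease filter is the right-to-left running maximum", {
  expect_identical(stepwise_decrease_filter(c(10, 10, 6, 2, 0)),
                   c(10, 10, 6, 2, 0))
  expect_identical(stepwise_decrease_filter(c(8, 10, 6, 7, 2)),
                   c(10, 10, 7, 7, 2))
  expect_identical(stepwise_decrease_filter(5), 5)
  expect_identical(stepwise_decrease_filter(numeric(0)), numeric(0))
})

test_that("the filter is idempotent and produces non-increasing output", {
  set.seed(77)
  for (k in 1:20) {
    x <- rpois(sample(3:15, 1), 20)
    f1 <- stepwise_decrease_filter(x)
    expect_true(all(diff(f1) <= 0))
    expect_identical(stepwise_decrease_filter(f1), f1)
    # raising happened exactly where needed: output >= raw, pointwise
    expect_true(all(f1 >= x))
    # and matches an independent right-to-left maximum
    oracle <- vapply(seq_along(x), function(i) max(x[i:length(x)]), numeric(1))
    expect_equal(f1, oracle)
  }
})

test_that("survival summaries compute the death-weighted mean lifespan", {
  s <- survival_summary(c(10, 10, 6, 2, 0), 0:4)
  expect_equal(unname(s$deaths_per_day[as.character(2:4)]), c(4, 4, 2))
  expect_equal(s$mean_lifespan, 2.8)
  expect_false(s$censored)

  s2 <- survival_summary(c(5, 0), c(0, 1))
  expect_equal(s2$mean_lifespan, 1)

  s3 <- survival_summary(c(8, 8, 8), 0:2)
  expect_true(is.na(s3$mean_lifespan))
  expect_true(s3$censored)
})

test_that("increasing counts are rejected before summarizing", {
  expect_error(survival_summary(c(5, 7, 3), 0:2), "filter")
})
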