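test_that("isolated single eggs anchor the detection priors", {
  p <- render_egg_plate(30, cluster_fraction = 0, debris_count = 0,
                        seed = 51)
  pri <- find_single_eggs(p$image)
  expect_gte(nrow(pri$singles), 25)
  true_area <- pi * mean(p$truth$eggs$a) * mean(p$truth$eggs$b)
  expect_lt(abs(pri$ref_area - true_area) / true_area, 0.15)
  expect_false(pri$low_confidence)
})

test_that("plates without plausible eggs abort or report zero appropriately", {
  # debris only: compact dark blobs exist, priors cannot be anchored
  pd <- render_egg_plate(0, debris_count = 8, seed = 52)
  expect_error(find_single_eggs(pd$image), class = "wv_no_priors")
  expect_error(count_eggs(pd$image), class = "wv_no_priors")

  # a truly empty plate counts zero
  pe <- render_egg_plate(0, debris_count = 0, seed = 53)
  expect_identical(count_eggs(pe$image)$n_eggs, 0L)
})

test_that("multi-thresholding processes the full level ladder", {
  p <- render_egg_plate(15, seed = 54)
  pri <- find_single_eggs(p$image)
  ep <- egg_params()
  expect_identical(length(ep$levels), 21L)    # 30..230 step 10
  raw <- multi_threshold_detect(p$image, pri, ep)
  expect_gt(nrow(raw), 0)
  expect_true(all(raw$level %in% ep$levels))
  expect_error(egg_params(levels = seq(30, 110, by = 10)), "at least 10")
})

test_that("a faint egg is only detected in a narrow band of levels", {
  p <- render_egg_plate(12, seed = 55, egg_intensity_range = c(70, 110))
  pri <- find_single_eggs(p$image)
  px <- p$image$pixels
  faint <- draw_pos <- c(60, 500)
  # paint one extra faint egg by hand at a known empty location
  th <- seq(0, 2 * pi, length.out = 400)
  for (rr in -4:4) for (cc in -6:6)
    if ((rr / 3.2)^2 + (cc / 5)^2 <= 1)
      px[faint[1] + rr, faint[2] + cc] <- 168
  raw <- multi_threshold_detect(gray_image(px), pri, egg_params())
  near <- raw[abs(raw$centroid_r - faint[1]) < 4 &
                abs(raw$centroid_c - faint[2]) < 4, ]
  expect_gte(nrow(near), 2)
  expect_true(all(near$level >= 170))      # visible only above its gray value
})

test_that("clustering merges replicates and drops single-level spurious hits", {
  pri <- structure(list(ref_gray = 110, ref_area = 50,
                        area_band = c(25, 75), ellipse_band = c(0.4, 0.9),
                        gray_range = c(60, 160)),
                   class = "egg_priors")
  raw <- data.frame(
    centroid_r = c(rep(50, 12) + rnorm(12, 0, 0.3), 80, 83, 120),
    centroid_c = c(rep(60, 12) + rnorm(12, 0, 0.3), 40, 40, 200),
    area = 50, level = c(seq(60, 170, by = 10), 90, 90, 100),
    from_clump = FALSE)
  res <- cluster_detections(raw, pri, egg_params(merge_radius = 2,
                                                 min_occurrences = 3))
  # the replicated egg survives with its occurrences; the two 3-px-apart
  # detections stay distinct; all of them fall below min_occurrences
  expect_identical(res$n_eggs, 1L)
  expect_identical(res$detections$occurrences, 12L)
  expect_identical(res$n_candidates_prefilter, 4L)
})

test_that("separated egg plates are counted exactly", {
  p <- render_egg_plate(30, cluster_fraction = 0, debris_count = 0,
                        seed = 56)
  expect_identical(count_eggs(p$image)$n_eggs, 30L)
})

test_that("clustered plates with debris are counted close to truth", {
  # smoke-level accuracy check; the full 42-plate envelope is asserted in
  # the acceptance suite
  errs <- vapply(1:4, function(k) {
    ne <- c(20, 35, 55, 70)[k]
    p <- render_egg_plate(ne, cluster_fraction = 0.3, debris_count = 8,
                          seed = 60 + k)
    abs(count_eggs(p$image)$n_eggs - ne)
  }, numeric(1))
  expect_true(all(errs <= 8))
  expect_lt(mean(errs), 5)
})

test_that("doubling the level density changes counts by less than 5 percent", {
  p <- render_egg_plate(40, cluster_fraction = 0.2, debris_count = 4,
                        seed = 57)
  n10 <- count_eggs(p$image, egg_params(levels = seq(30, 230, by = 10)))$n_eggs
  n5 <- count_eggs(p$image, egg_params(levels = seq(30, 230, by = 5)))$n_eggs
  expect_lt(abs(n5 - n10) / n10, 0.05)
})

test_that("output count never exceeds the raw spatial clusters", {
  p <- render_egg_plate(25, cluster_fraction = 0.3, debris_count = 5,
                        seed = 58)
  res <- count_eggs(p$image)
  expect_lte(res$n_eggs, res$n_candidates_prefilter)
})

test_that("egg-laying rate follows the assay arithmetic", {
  expect_equal(egg_laying_rate(90, 10, minutes = 90), 6)
})
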