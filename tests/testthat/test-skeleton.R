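test_that("a thick bar thins to a branch-free two-endpoint curve", {
  bar <- matrix(FALSE, 9, 101); bar[3:7, ] <- TRUE
  s <- skeletonize(bar)
  expect_identical(s$branch_count, 0L)
  expect_identical(nrow(s$endpoints), 2L)
  expect_true(s$traceable)
  # thinning erodes at most about half the bar height from each end
  expect_gte(diff(range(s$path[, "col"])), 101 - 9)
  # single center row
  expect_true(all(s$path[, "row"] == 5))
})

test_that("a plus-sign shape produces a branched (invalid-worm) skeleton", {
  pl <- matrix(FALSE, 41, 41)
  pl[19:23, ] <- TRUE; pl[, 19:23] <- TRUE
  expect_gte(skeletonize(pl)$branch_count, 1L)
})

test_that("a disk collapses to a degenerate skeleton", {
  dk <- fix_disk_mask(c(25, 25), c(13, 13), 10)
  s <- skeletonize(dk)
  expect_lt(nrow(s$pixels), 5)
})

test_that("empty masks are rejected", {
  expect_error(skeletonize(matrix(FALSE, 5, 5)), "empty")
})

test_that("skeleton pixels always lie inside the source mask", {
  set.seed(31)
  for (k in 1:5) {
    m <- fix_disk_mask(c(40, 40), c(20, 20), 6 + k)
    m[10:30, 12:18] <- TRUE   # add a limb
    s <- skeletonize(m)
    expect_true(all(m[s$pixels]))
  }
})

test_that("skeletonizing a skeleton changes nothing", {
  bar <- matrix(FALSE, 9, 80); bar[3:7, ] <- TRUE
  s1 <- skeletonize(bar)
  m2 <- matrix(FALSE, 9, 80); m2[s1$pixels] <- TRUE
  s2 <- skeletonize(m2)
  expect_setequal(paste(s1$pixels[, 1], s1$pixels[, 2]),
                  paste(s2$pixels[, 1], s2$pixels[, 2]))
})

test_that("pixel-traced length follows the horizontal/diagonal step rule", {
  run <- matrix(FALSE, 3, 101); run[2, ] <- TRUE
  expect_equal(skeleton_length(skeletonize(run)), 100)

  dg <- matrix(FALSE, 103, 103)
  for (i in 1:101) dg[i + 1, i + 1] <- TRUE
  expect_equal(skeleton_length(skeletonize(dg)), 100 * sqrt(2))

  # L-shaped path: 51 + 51 pixels sharing the corner pixel, given as an
  # explicit ordered path (100 axis-aligned unit steps)
  L_path <- rbind(cbind(60:10, 10), cbind(10, 11:60))
  expect_equal(skeleton_length(L_path), 100)
})

test_that("branched skeletons refuse a length", {
  pl <- matrix(FALSE, 41, 41)
  pl[19:23, ] <- TRUE; pl[, 19:23] <- TRUE
  expect_error(skeleton_length(skeletonize(pl)), "branch")
})

test_that("spur pruning removes short side branches only", {
  bar <- matrix(FALSE, 15, 80); bar[7, 5:75] <- TRUE
  bar[8:10, 40] <- TRUE               # 3-px spur
  s0 <- skeletonize(bar, prune = 0)
  expect_gte(s0$branch_count, 1L)
  s1 <- skeletonize(bar, prune = 5)
  expect_identical(s1$branch_count, 0L)
  expect_identical(nrow(s1$endpoints), 2L)
})
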