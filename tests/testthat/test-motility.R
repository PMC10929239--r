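# Binarization, pixel-change classification and the motility index.

test_that("binarization methods behave on constructed images", {
  const <- image_stack(array(100, c(2, 8, 8)), axes = "TYX", pixel_size = 1,
                       frame_interval = 1)
  bin <- binarize(const, "fixed", value = 50)
  expect_true(all(bin$masks))
  two <- matrix(20, 16, 16); two[5:12, 5:12] <- 200
  st2 <- image_stack(aperm(array(rep(two, 2), c(16, 16, 2)), c(3, 1, 2)),
                     axes = "TYX", pixel_size = 1, frame_interval = 1)
  bin2 <- binarize(st2, "otsu_global")
  expect_gt(bin2$thresholds[1], 20)
  expect_lt(bin2$thresholds[1], 200)
  expect_equal(sum(bin2$masks[1, , ]), 64)
  zero <- image_stack(array(0, c(2, 8, 8)), axes = "TYX", pixel_size = 1,
                      frame_interval = 1)
  expect_warning(bz <- binarize(zero, "fixed", value = 10), "empty")
  expect_false(any(bz$masks))
  expect_error(binarize(const, "fixed"), "threshold value")
})

test_that("pixel changes match hand-enumerated set differences", {
  m0 <- mask_from_coords(c(3, 4), list(c(1, 1), c(1, 2)))
  m1 <- mask_from_coords(c(3, 4), list(c(1, 2), c(1, 3)))
  cc <- classify_pixel_changes(m0, m1)
  expect_equal(cc$extend, 1)
  expect_equal(cc$retract, 1)
  expect_equal(cc$stable, 1)
  same <- mask_from_coords(c(4, 4), list(c(1, 1), c(2, 2), c(3, 3), c(4, 4), c(1, 4)))
  expect_equal(unclass(classify_pixel_changes(same, same))[c("extend", "retract", "stable")],
               list(extend = 0L, retract = 0L, stable = 5L))
  empty <- matrix(FALSE, 4, 4)
  one <- mask_from_coords(c(4, 4), list(c(2, 2)))
  cc2 <- classify_pixel_changes(empty, one)
  expect_equal(c(cc2$extend, cc2$retract, cc2$stable), c(1, 0, 0))
  expect_error(classify_pixel_changes(empty, matrix(FALSE, 3, 3)), "shape")
})

test_that("classification agrees with the brute-force oracle on random masks", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      a <- matrix(stats::runif(64 * 64) < 0.3, 64)
      b <- matrix(stats::runif(64 * 64) < 0.3, 64)
      cc <- classify_pixel_changes(a, b)
      bf <- brute_force_changes(a, b)
      expect_identical(cc$extend, bf$extend)
      expect_identical(cc$retract, bf$retract)
      expect_identical(cc$stable, bf$stable)
      expect_identical(cc$extend + cc$stable, sum(b))
      expect_identical(cc$retract + cc$stable, sum(a))
    }
  })
})

test_that("the motility index follows its formula and encodes the undefined case", {
  expect_equal(motility_index(list(extend = 1, retract = 1, stable = 1)), 2)
  expect_equal(motility_index(list(extend = 0, retract = 0, stable = 5)), 0)
  expect_true(is.na(motility_index(list(extend = 3, retract = 0, stable = 0))))
})

test_that("the index is invariant under equal translation of both masks", {
  withr::with_seed(31, {
    a <- matrix(stats::runif(48 * 48) < 0.2, 48)
    b <- matrix(stats::runif(48 * 48) < 0.2, 48)
    # clear the borders so translation loses no pixels
    a[c(1:5, 44:48), ] <- FALSE; a[, c(1:5, 44:48)] <- FALSE
    b[c(1:5, 44:48), ] <- FALSE; b[, c(1:5, 44:48)] <- FALSE
    i0 <- motility_index(classify_pixel_changes(a, b))
    at <- microgliaQuant:::mat_shift(a, 3, -2, FALSE)
    bt <- microgliaQuant:::mat_shift(b, 3, -2, FALSE)
    expect_equal(motility_index(classify_pixel_changes(at, bt)), i0)
  })
})

test_that("a static lapse has zero mean index over all pairs", {
  cfg <- small_cfg(seed = 3, n_frames = 5)
  sim <- simulate_baseline_timelapse(cfg, 0)
  res <- timelapse_motility(sim$stack)
  expect_equal(res$mean_index, 0)
  expect_equal(res$n_pairs, 4)
  expect_equal(res$excluded_pairs, 0)
  expect_true(res$valid)
})

test_that("pipeline indices equal ground-truth indices at zero noise", {
  cfg <- small_cfg(seed = 13, n_frames = 8)
  sim <- simulate_baseline_timelapse(cfg, 0.1)
  res <- timelapse_motility(sim$stack)
  truth <- sim$truth$per_pair_change_counts
  expect_equal(res$per_pair_index,
               (truth$extend + truth$retract) / truth$stable)
  expect_identical(res$counts$extend, truth$extend)
  expect_identical(res$counts$retract, truth$retract)
  expect_identical(res$counts$stable, truth$stable)
})

test_that("mean index increases with the programmed turnover rate", {
  means <- vapply(c(0.03, 0.12), function(r) {
    vals <- vapply(1:3, function(s) {
      sim <- simulate_baseline_timelapse(small_cfg(seed = s, n_frames = 6), r)
      timelapse_motility(sim$stack)$mean_index
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_lt(means[1], means[2])
})

test_that("an all-undefined lapse is flagged invalid", {
  # foreground appears only in disjoint single frames: stable is always 0
  arr <- array(0, c(3, 8, 8))
  arr[1, 2, 2] <- 200; arr[2, 6, 6] <- 200; arr[3, 2, 6] <- 200
  st <- image_stack(arr, axes = "TYX", pixel_size = 1, frame_interval = 1)
  res <- timelapse_motility(st, method = "fixed", value = 100, register = FALSE)
  expect_false(res$valid)
  expect_true(is.na(res$mean_index))
  expect_equal(res$excluded_pairs, 2)
})
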