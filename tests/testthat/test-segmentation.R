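test_that("single erosion matches elementary morphology", {
  m <- array(FALSE, c(3, 3, 1)); m[, , 1] <- TRUE
  e <- erode_once(m)
  expect_equal(sum(e), 1)
  expect_true(e[2, 2, 1])

  single <- array(FALSE, c(5, 5, 1)); single[3, 3, 1] <- TRUE
  expect_equal(sum(erode_once(single)), 0)

  big <- array(FALSE, c(12, 12, 2)); big[2:11, 2:11, ] <- TRUE
  e2 <- erode_once(big)
  expect_equal(sum(e2[, , 1]), 64)   # 10x10 solid -> 8x8 interior
  expect_true(all(e2[3:10, 3:10, ]))
})

test_that("erosion equals the brute-force neighbourhood oracle on random masks", {
  set.seed(77)
  for (trial in 1:100) {
    d <- c(sample(4:9, 1), sample(4:9, 1), sample(1:3, 1))
    m <- array(runif(prod(d)) > 0.5, d)
    expect_identical(erode_once(m), oracle_erode(m))
  }
})

test_that("bilateral merge requires disjoint masks", {
  d <- c(6, 6, 2)
  left <- array(FALSE, d); left[, 1:3, ] <- TRUE
  right <- array(FALSE, d); right[, 4:6, ] <- TRUE
  merged <- merge_bilateral(left, right)
  expect_equal(sum(merged), sum(left) + sum(right))
  empty <- array(FALSE, d)
  expect_equal(merge_bilateral(empty, right), right)
  expect_error(merge_bilateral(left, left), "overlap")
})

test_that("FSF threshold windows match brute-force filtering and nest", {
  set.seed(5)
  d <- c(8, 8, 3)
  vals <- array(runif(prod(d), 0, 100), d)
  fv <- fsf_volume(vals, array(TRUE, d))
  mask <- array(runif(prod(d)) > 0.3, d)

  t40 <- apply_fsf_threshold(fv, mask, 40, 100)
  brute <- mask & vals >= 40 & vals <= 100
  expect_identical(t40, brute)

  t0 <- apply_fsf_threshold(fv, mask, 0, 100)
  expect_identical(t0, mask)
  t50 <- apply_fsf_threshold(fv, mask, 50, 100)
  expect_true(all(t50[t50] & t40[t50]))       # 50-100 subset of 40-100
  expect_true(all(!(t50 & !t40)))
  expect_true(all(!(t40 & !t0)))
  expect_error(apply_fsf_threshold(fv, mask, 60, 40), "lo < hi")
})

test_that("ROI construction respects seeds, validity and the display window", {
  ph <- make_phantom(phantom_config(grid_dim = c(48, 48, 7)), seed = 9)
  tr <- ph$truth
  fv <- fsf_volume(tr$baseline_fsf, !is.na(tr$baseline_fsf))
  seeds <- list(bat_left = tr$masks$bat_left, bat_right = tr$masks$bat_right,
                sat = tr$masks$sat, muscle = tr$masks$muscle)
  roi <- build_roi(fv, seeds, display_window = c(30, 80))
  # masks contained in their seeds and pairwise disjoint
  for (nm in names(seeds))
    expect_true(all(seeds[[nm]][roi$masks[[nm]]]))
  both <- roi$masks$bat_left & roi$masks$bat_right
  expect_false(any(both))
  # window trims only boundary voxels outside 30-80%
  bat_all <- merge_bilateral(roi$masks$bat_left, roi$masks$bat_right)
  seed_all <- merge_bilateral(seeds$bat_left, seeds$bat_right)
  dice <- 2 * sum(bat_all & seed_all) / (sum(bat_all) + sum(seed_all))
  expect_gt(dice, 0.9)
  trimmed <- seed_all & !bat_all
  if (any(trimmed))
    expect_true(all(fv$fsf[trimmed] < 30 | fv$fsf[trimmed] > 80))

  # window (0, 100) leaves the seeds untouched
  roi_full <- build_roi(fv, seeds, display_window = c(0, 100))
  expect_identical(roi_full$masks$bat_left, seeds$bat_left)

  merged <- merge_roi_sides(roi)
  expect_true(merged$merged)
  expect_null(merged$masks$bat_left)

  expect_error(build_roi(fv, list(bat = array(FALSE, dim(fv$fsf)))), "empty")
  all_invalid <- fsf_volume(array(NA_real_, dim(fv$fsf)),
                            array(FALSE, dim(fv$fsf)))
  expect_error(build_roi(all_invalid, seeds), "no valid")
})
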