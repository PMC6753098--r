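test_that("noiseless single voxels are inverted exactly", {
  # pure water
  ser <- drop_leading_train_echoes(make_test_series(0, psi = 0, r2s = 0))
  res <- separate_fat_water(ser, fat_spectrum(),
                            separation_options(fit_threshold_frac = 0))
  expect_lt(res$F[1] / (res$F[1] + res$W[1]), 1e-9)

  # mixed voxel with field offset and decay
  ser2 <- drop_leading_train_echoes(make_test_series(40, psi = 30, r2s = 40))
  res2 <- separate_fat_water(ser2, fat_spectrum(),
                             separation_options(fit_threshold_frac = 0))
  fsf2 <- compute_fsf_map(res2, background_threshold_frac = 0)
  expect_equal(fsf2$fsf[1, 1, 1], 40, tolerance = 0.01)
  expect_equal(res2$psi[1], 30, tolerance = 0.1)
})

test_that("noiseless parameters are recovered across the FSF range", {
  fsfs <- seq(0, 100, by = 10)
  ser <- drop_leading_train_echoes(make_test_series(fsfs, psi = 25, r2s = 40))
  res <- separate_fat_water(ser, fat_spectrum(),
                            separation_options(fit_threshold_frac = 0))
  for (i in seq_along(fsfs)) {
    expect_lt(abs(res$W[i] - 100 * (1 - fsfs[i] / 100)) / 100, 1e-3)
    expect_lt(abs(res$F[i] - fsfs[i]) / 100, 1e-3)
    expect_lt(abs(res$psi[i] - 25), 0.1)
    expect_lt(abs(res$r2star[i] - 40), 0.05)
  }
})

test_that("a smooth field map over a slab is recovered without swaps", {
  ph <- make_phantom(phantom_config(), seed = 5)
  tr <- ph$truth
  fsf <- tr$baseline_fsf; fsf[is.na(fsf)] <- 0
  ser <- drop_leading_train_echoes(
    synthesize_echoes(fsf, tr$m0, tr$field_map_hz, tr$r2star,
                      build_echo_schedule(), fat_spectrum()))
  res <- separate_fat_water(ser, fat_spectrum())
  fm <- compute_fsf_map(res)
  body <- tr$masks$body & fm$valid
  err <- fm$fsf[body] - tr$baseline_fsf[body]
  expect_lt(mean(abs(err) > 50), 0.001)   # swap fraction
  expect_lt(mean(abs(err)), 0.05)         # noiseless accuracy
  expect_lt(sqrt(mean((res$psi[body] - tr$field_map_hz[body])^2)), 1)
})

test_that("SNR-50 slab separation stays within one percentage point", {
  ph <- make_phantom(phantom_config(), seed = 6)
  tr <- ph$truth
  fsf <- tr$baseline_fsf; fsf[is.na(fsf)] <- 0
  ser <- drop_leading_train_echoes(
    synthesize_echoes(fsf, tr$m0, tr$field_map_hz, tr$r2star,
                      build_echo_schedule(), fat_spectrum(),
                      noise_sd = 2, seed = 8))
  res <- separate_fat_water(ser, fat_spectrum())
  fm <- compute_fsf_map(res)
  body <- tr$masks$body & fm$valid
  expect_lt(mean(abs(fm$fsf[body] - tr$baseline_fsf[body])), 1)
})

test_that("dominant-signal branches agree and masking is bookkept", {
  # branch identity on exact inputs
  d <- c(2, 1, 1)
  res <- structure(list(W = array(c(40, 100), d), F = array(c(60, 0), d),
                        total = array(100, d),
                        psi = array(0, d), r2star = array(0, d),
                        residual = array(0, d), valid = array(TRUE, d),
                        mag1 = array(100, d), voxel_mm = c(1.25, 1.25, 4)),
                   class = "separation_result")
  fm <- compute_fsf_map(res, background_threshold_frac = 0)
  expect_equal(fm$fsf[1, 1, 1], 60)   # fat-dominant branch
  expect_equal(fm$fsf[2, 1, 1], 0)    # water-dominant branch

  # all-zero voxel: flagged invalid, not fitted
  dat <- array(0i, c(2, 1, 1, 15))
  dat[1, 1, 1, ] <- 100
  ser <- echo_series(dat, drop_leading_train_echoes(build_echo_schedule()))
  res2 <- separate_fat_water(ser, fat_spectrum())
  expect_false(res2$valid[2, 1, 1])
  expect_true(res2$valid[1, 1, 1])
  fm2 <- compute_fsf_map(res2)
  expect_true(is.na(fm2$fsf[2, 1, 1]))
  # valid + invalid voxels partition the grid
  expect_equal(sum(fm2$valid) + sum(!fm2$valid), length(fm2$valid))

  # erroneous out-of-range separation results are masked, not clipped
  res$W[1] <- -10
  fm3 <- compute_fsf_map(res, background_threshold_frac = 0)
  expect_true(is.na(fm3$fsf[1, 1, 1]))
  expect_false(fm3$valid[1, 1, 1])
})

test_that("magnitude-only fitting mode recovers noiseless fractions", {
  ser <- drop_leading_train_echoes(make_test_series(c(20, 70), psi = 0, r2s = 45))
  res <- separate_fat_water(ser, fat_spectrum(),
                            separation_options(fitting = "magnitude",
                                               fit_threshold_frac = 0))
  fm <- compute_fsf_map(res, background_threshold_frac = 0)
  expect_equal(fm$fsf[1, 1, 1], 20, tolerance = 1)
  expect_equal(fm$fsf[2, 1, 1], 70, tolerance = 1)
})

test_that("separation refuses degenerate inputs", {
  dat <- array(1 + 0i, c(1, 1, 1, 3))
  sched <- build_echo_schedule(3, 1, 1, 1)
  ser <- echo_series(dat, sched)
  expect_error(separate_fat_water(ser), "4 echoes")
})
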