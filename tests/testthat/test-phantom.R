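test_that("phantom baseline statistics match the configured tissue values", {
  ph <- make_phantom(phantom_config(), seed = 1)
  tr <- ph$truth
  bat <- tr$masks$bat
  vals <- tr$baseline_fsf[bat]
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 52.7), se)
  expect_lt(abs(mean(tr$baseline_fsf[tr$masks$sat]) - 89.3), 0.75)
  # every decade is populated with at least 60 BAT voxels
  counts <- tabulate(pmin(floor(vals / 10), 9) + 1, 10)
  expect_true(all(counts >= 60))
  # labels partition the body; default 15 slices
  expect_equal(dim(ph$labels$labels)[3], 15)
  expect_true(all(ph$labels$labels %in% 0:3))
  expect_true(all(tr$baseline_fsf[tr$masks$body] >= 0 &
                    tr$baseline_fsf[tr$masks$body] <= 100))
})

test_that("degenerate spread collapses BAT onto the mean; phantom is deterministic", {
  cfg <- phantom_config(bat_fsf_spread = 0)
  ph <- make_phantom(cfg, seed = 3)
  vals <- ph$truth$baseline_fsf[ph$truth$masks$bat]
  expect_true(all(vals == 52.7))

  a <- make_phantom(phantom_config(), seed = 11)
  b <- make_phantom(phantom_config(), seed = 11)
  expect_identical(a$truth$baseline_fsf, b$truth$baseline_fsf)
  expect_identical(a$labels$labels, b$labels$labels)

  expect_error(phantom_config(sat_fsf_sd = -1), "sat_fsf_sd")
  expect_error(phantom_config(grid_dim = c(4, 4)), "grid_dim")
})

test_that("cooling response follows decade slopes, stays in range, is monotone", {
  ph <- make_phantom(phantom_config(), seed = 2)
  tr <- ph$truth
  ref <- tr$reference_dose
  doses <- c(0, ref / 2, ref)
  # zero dose leaves the baseline untouched
  f0 <- simulate_cooling_response(tr, c(0, 0))
  expect_equal(f0[, , , 2], tr$baseline_fsf)

  fs <- simulate_cooling_response(tr, doses)
  expect_true(all(fs[!is.na(fs)] >= 0 & fs[!is.na(fs)] <= 100))
  dec <- floor(tr$baseline_fsf / 10)
  chg <- function(d_sel, a) {
    sel <- tr$masks$bat & !is.na(dec) & dec %in% d_sel
    mean(fs[, , , a][sel] - tr$baseline_fsf[sel])
  }
  # full protocol dose realizes the configured endpoint changes
  expect_equal(chg(9, 3), -14.4, tolerance = 0.15)
  expect_equal(chg(0, 3), 6.7, tolerance = 0.15)
  # noise-free decade-conditional monotonicity in dose
  for (a in 2:3) {
    expect_lte(chg(6:9, a), chg(6:9, a - 1) + 1e-9)
    expect_gte(chg(0:2, a), chg(0:2, a - 1) - 1e-9)
  }
  expect_error(simulate_cooling_response(tr, c(0, 5, 3)), "nondecreasing")
  expect_error(simulate_cooling_response(tr, c(1, 2)), "start")
})

test_that("echo synthesis matches the closed-form signal model", {
  sched <- build_echo_schedule()
  sp <- fat_spectrum()
  te_s <- sched$te_ms / 1000

  # pure water, no field offset or decay: constant magnitude across echoes
  ser <- make_test_series(0, psi = 0, r2s = 0)
  expect_equal(Mod(ser$data[1, 1, 1, ]), rep(100, 18), tolerance = 1e-12)

  # pure fat with a single-peak spectrum: constant magnitude, linear phase
  sp1 <- fat_spectrum(ppm = 1.30, rel_amp = 1)
  ser1 <- synthesize_echoes(array(100, c(1, 1, 1)), array(100, c(1, 1, 1)),
                            array(10, c(1, 1, 1)), array(0, c(1, 1, 1)),
                            sched, sp1)
  expect_equal(Mod(ser1$data[1, 1, 1, ]), rep(100, 18), tolerance = 1e-9)
  df <- sp1$freq_offset_hz + 10
  expect_equal(Arg(ser1$data[1, 1, 1, ]),
               ((2 * pi * df * te_s + pi) %% (2 * pi)) - pi,
               tolerance = 1e-9)

  # general voxel against an independently coded forward oracle
  set.seed(7)
  for (i in 1:25) {
    fsf <- runif(1, 0, 100); psi <- runif(1, -60, 60); r2s <- runif(1, 10, 80)
    ser2 <- make_test_series(fsf, psi = psi, r2s = r2s)
    want <- oracle_signal(100 * (1 - fsf / 100), fsf, psi, r2s, te_s,
                          sp$rel_amp, sp$freq_offset_hz)
    expect_equal(ser2$data[1, 1, 1, ], want, tolerance = 1e-12)
  }

  expect_error(make_test_series(120), "FSF")
})

test_that("oracle equivalence holds across a large random voxel batch", {
  sched <- build_echo_schedule()
  sp <- fat_spectrum()
  te_s <- sched$te_ms / 1000
  set.seed(42)
  n <- 1000
  fsf <- runif(n, 0, 100); psi <- runif(n, -200, 200); r2s <- runif(n, 0, 120)
  ser <- synthesize_echoes(array(fsf, c(n, 1, 1)), array(100, c(n, 1, 1)),
                           array(psi, c(n, 1, 1)), array(r2s, c(n, 1, 1)),
                           sched, sp)
  idx <- sample(n, 50)
  for (i in idx) {
    want <- oracle_signal(100 * (1 - fsf[i] / 100), fsf[i], psi[i], r2s[i],
                          te_s, sp$rel_amp, sp$freq_offset_hz)
    expect_equal(ser$data[i, 1, 1, ], want, tolerance = 1e-12)
  }
})

test_that("motion warps all echoes together and reports the true field", {
  ph <- make_phantom(phantom_config(grid_dim = c(32, 32, 5)), seed = 4)
  tr <- ph$truth
  fsf <- tr$baseline_fsf; fsf[is.na(fsf)] <- 0
  ser <- synthesize_echoes(fsf, tr$m0, tr$field_map_hz, tr$r2star,
                           build_echo_schedule(6, 1, 1, 1), fat_spectrum())

  no <- apply_motion(ser, list(type = "none"))
  expect_identical(no$series$data, ser$data)
  expect_true(all(no$field == 0))
  z <- apply_motion(ser, list(type = "smooth", amplitude = 0))
  expect_identical(z$series$data, ser$data)

  # a pure (3, 4) in-plane translation displaces every point by 5 voxels
  t34 <- apply_motion(ser, list(type = "translation", shift = c(3, 4, 0)))
  mag <- sqrt(t34$field[, , , 1]^2 + t34$field[, , , 2]^2)
  expect_true(all(abs(mag - 5) < 1e-12))
  expect_equal(t34$series$data[1, 1, 1, 3], ser$data[4, 5, 1, 3])

  a <- apply_motion(ser, list(type = "smooth", amplitude = 2), seed = 5)
  b <- apply_motion(ser, list(type = "smooth", amplitude = 2), seed = 5)
  expect_identical(a$series$data, b$series$data)
  expect_true(max(abs(a$field)) <= 2 + 1e-12)

  expect_error(apply_motion(ser, list(type = "translation", shift = c(40, 0, 0))),
               "exceeds")
  expect_error(apply_motion(ser, list(type = "smooth", amplitude = 50)),
               "amplitude")
})

test_that("cooling protocol descends through the personalized phases", {
  pr <- simulate_cooling_protocol(15.6, 32, 60, seed = 1)
  prof <- pr$profile
  expect_equal(prof$set_temp_C[nrow(prof)], 18.6)
  expect_equal(diff(prof$time_s)[1], 30)
  expect_equal(prof$set_temp_C[prof$time_s == 9 * 60], 21.6)
  expect_equal(prof$set_temp_C[1], 32)
  # sensation: integer 0..50, starts neutral, never increases
  s <- pr$sensation$sensation
  expect_true(all(s >= 0 & s <= 50))
  expect_equal(s[1], 50)
  expect_true(all(diff(s) <= 0))

  single <- simulate_cooling_protocol(15.6, 32, 0)
  expect_equal(nrow(single$profile), 1)
  expect_equal(single$profile$set_temp_C, 32)

  again <- simulate_cooling_protocol(15.6, 32, 60, seed = 1)
  expect_identical(pr$sensation$sensation, again$sensation$sensation)

  expect_error(simulate_cooling_protocol(30, 32, 60), "thermoneutral")
  expect_error(simulate_cooling_protocol(15.6, 32, -5), "duration")
})
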