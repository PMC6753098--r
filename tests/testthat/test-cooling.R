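ramp_profile <- function() {
  # linear descent 32 -> 10 degC over 60 min, 30 s cadence
  t_s <- seq(0, 3600, by = 30)
  cooling_profile(t_s, 32 - 22 * t_s / 3600, thermoneutral_C = 32)
}

test_that("DuBois BSA reproduces reference anthropometrics", {
  expect_equal(round(dubois_bsa(70.8, 170.6), 2), 1.82)
  expect_equal(round(dubois_bsa(55.8, 162.0), 2), 1.59)
  expect_equal(dubois_bsa(70.8, 170.6),
               0.007184 * 70.8^0.425 * 170.6^0.725)
  expect_error(dubois_bsa(0, 170), "positive")
  expect_error(dubois_bsa(70, -1), "positive")
})

test_that("cooling dose integrates the relative temperature curve", {
  # constant thermoneutral profile: zero dose
  flat <- cooling_profile(seq(0, 600, 30), rep(32, 21), thermoneutral_C = 32)
  expect_equal(cooling_dose(flat, 0, 10), 0)

  # linear ramp: triangle area 0.5 * 22 * 60
  expect_equal(cooling_dose(ramp_profile(), 0, 60), 660, tolerance = 1e-9)

  # step: rectangle area 22 * 60
  t_s <- seq(0, 3660, by = 30)
  step <- cooling_profile(t_s, ifelse(t_s == 0, 32, 10), thermoneutral_C = 32)
  expect_equal(cooling_dose(step, 1, 61), 22 * 60)

  # step dose dominates the linear dose for equal endpoints
  expect_gt(cooling_dose(step, 1, 61), cooling_dose(ramp_profile(), 0, 60))

  expect_error(cooling_dose(ramp_profile(), 10, 5), "t1 < t2")
  expect_error(cooling_dose(ramp_profile(), -5, 10), "span")
})

test_that("dose additivity, monotonicity and BSA scaling identities hold", {
  pr <- ramp_profile()
  d13 <- cooling_dose(pr, 0, 45)
  expect_equal(cooling_dose(pr, 0, 17.3) + cooling_dose(pr, 17.3, 45), d13,
               tolerance = 1e-9)
  # cumulative dose nondecreasing when T <= T0
  cum <- vapply(seq(5, 60, 5), function(t2) cooling_dose(pr, 0, t2), 1)
  expect_true(all(diff(cum) > 0))
  # doubling BSA halves the normalized dose exactly
  expect_equal(normalized_cooling_dose(pr, 2 * 1.82, 0, 60),
               normalized_cooling_dose(pr, 1.82, 0, 60) / 2)
  expect_equal(normalized_cooling_dose(pr, 1.82, 0, 60), 660 / 1.82)
  expect_error(normalized_cooling_dose(pr, 0, 0, 60), "positive")
  # a floor of zero ignores rewarming excursions
  warm <- cooling_profile(c(0, 60, 120), c(32, 40, 32), thermoneutral_C = 32)
  expect_equal(cooling_dose(warm, 0, 2, integrand_floor = 0), 0)
  expect_lt(cooling_dose(warm, 0, 2), 0)
})

test_that("log synchronization aligns doses and sensations to scan midpoints", {
  t_s <- seq(0, 3600, by = 30)
  pr <- cooling_profile(t_s, c(rep(32, 21), rep(22, 100)), thermoneutral_C = 32)
  sens <- sensation_log(t_s, as.integer(round(seq(50, 10, length.out = 121))))

  tab <- sync_logs(pr, sens, acquisition_times_s = c(0, 1200, 2400),
                   bsa_m2 = 2, scan_duration_s = 0)
  expect_equal(tab$cum_dose[1], 0)
  expect_equal(tab$sensation[1], 50)
  # acquisition aligned to a log sample: exact trapezoid of the step profile
  expect_equal(tab$cum_dose[2], 10 * (1200 - 630) / 60 + 0.5 * 10 * 0.5,
               tolerance = 1e-9)
  expect_equal(tab$cum_norm_dose[2], tab$cum_dose[2] / 2)
  expect_equal(tab$sensation[3], sens$sensation[max(which(t_s <= 2400))])

  expect_error(sync_logs(pr, sens, c(1200, 600), 2), "increasing")
  expect_error(sync_logs(pr, sens, c(-50, 600), 2), "span")
})

test_that("reference dose matches the closed-form phase areas", {
  ref <- reference_cooling_dose(15.6, 32, 60, phase_min = 8, endpoint_min = 64,
                                mass_kg = 70.8, height_cm = 170.6)
  want <- (8 * (32 - 21.6) + (64 - 16) * (32 - 18.6)) / dubois_bsa(70.8, 170.6)
  expect_equal(ref, want, tolerance = 1e-12)
})

test_that("constructors validate their invariants", {
  expect_error(cooling_profile(c(0, 0), c(32, 32)), "increasing")
  expect_error(sensation_log(c(0, 30), c(10, 60)), "0, 50")
  expect_silent(sensation_log(c(0, 30), c(50L, 0L)))
})
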