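# Cold-stress quantification: DuBois body surface area, cooling dose (area
# under the relative water-temperature curve), its BSA-normalized form, and
# synchronization of temperature/sensation logs to image acquisitions.

#' Cooling profile constructor
#'
#' Timestamped blanket water temperatures with their thermoneutral
#' reference T0.
#'
#' @param time_s sample times (s), strictly increasing.
#' @param set_temp_C set water temperature (degC).
#' @param actual_temp_C actual water temperature (degC).
#' @param thermoneutral_C thermoneutral reference temperature T0 (degC).
#' @return data.frame of class `cooling_profile` with attribute
#'   `thermoneutral_C`.
#' @export
cooling_profile <- function(time_s, set_temp_C, actual_temp_C = set_temp_C,
                            thermoneutral_C = set_temp_C[1]) {
  if (length(time_s) < 1L || any(diff(time_s) <= 0))
    stop_cfg("profile times must be strictly increasing")
  if (length(set_temp_C) != length(time_s) ||
      length(actual_temp_C) != length(time_s))
    stop_cfg("temperature vectors must match time vector length")
  structure(data.frame(time_s = time_s, set_temp_C = set_temp_C,
                       actual_temp_C = actual_temp_C),
            thermoneutral_C = thermoneutral_C,
            class = c("cooling_profile", "data.frame"))
}

#' Thermal sensation log constructor
#'
#' Self-reported cold perception on the 0 (very cold) to 50 (neutral)
#' integer scale.
#'
#' @param time_s sample times (s), strictly increasing.
#' @param sensation integer sensation values in [0, 50].
#' @return data.frame of class `sensation_log`.
#' @export
sensation_log <- function(time_s, sensation) {
  if (length(time_s) < 1L || any(diff(time_s) <= 0))
    stop_cfg("sensation times must be strictly increasing")
  if (any(sensation < 0 | sensation > 50))
    stop_cfg("sensation values must lie in [0, 50]")
  structure(data.frame(time_s = time_s, sensation = as.integer(sensation)),
            class = c("sensation_log", "data.frame"))
}

#' DuBois and DuBois body surface area
#'
#' `BSA = 0.007184 * mass^0.425 * height^0.725` (mass in kg, height in cm).
#'
#' @param mass_kg body mass (kg), positive.
#' @param height_cm body height (cm), positive.
#' @return body surface area in m^2.
#' @examples
#' round(dubois_bsa(70.8, 170.6), 2)  # 1.82
#' @export
dubois_bsa <- function(mass_kg, height_cm) {
  if (any(!is.finite(mass_kg)) || any(mass_kg <= 0)) stop_cfg("mass must be positive")
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) stop_cfg("height must be positive")
  0.007184 * mass_kg^0.425 * height_cm^0.725
}

#' Cooling dose over a time interval
#'
#' Trapezoidal integral of the relative water temperature `T0 - T(t)` over
#' `[t1, t2]` (minutes), in degC min. By default the signed relative
#' temperature is integrated, so intervals warmer than thermoneutral
#' subtract from the dose; a floor (e.g. 0) can be imposed on the integrand.
#'
#' @param profile a [cooling_profile()].
#' @param t1_min,t2_min integration bounds in minutes, within the log span.
#' @param temperature integrate `"actual"` (default) or `"set"` temperature.
#' @param integrand_floor lower bound applied to `T0 - T(t)` before
#'   integration; `-Inf` (default) integrates signed values.
#' @return cooling dose (degC min).
#' @export
cooling_dose <- function(profile, t1_min, t2_min, temperature = c("actual", "set"),
                         integrand_floor = -Inf) {
  temperature <- match.arg(temperature)
  t_min <- profile$time_s / 60
  if (t1_min >= t2_min) stop_cfg("need t1 < t2")
  if (t1_min < min(t_min) - 1e-9 || t2_min > max(t_min) + 1e-9)
    stop_cfg("integration range outside the profile span")
  T0 <- attr(profile, "thermoneutral_C")
  temp <- if (temperature == "actual") profile$actual_temp_C else profile$set_temp_C
  rel <- pmax(T0 - temp, integrand_floor)
  tt <- c(t1_min, t_min[t_min > t1_min & t_min < t2_min], t2_min)
  vv <- stats::approx(t_min, rel, xout = tt, rule = 2)$y
  sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2)
}

#' Normalized cooling dose
#'
#' Cooling dose divided by DuBois body surface area, in degC min m^-2; the
#' body-size-standardized measure of delivered cold stress.
#'
#' @inheritParams cooling_dose
#' @param bsa_m2 body surface area (m^2), positive.
#' @param ... passed to [cooling_dose()].
#' @return normalized cooling dose (degC min m^-2).
#' @export
normalized_cooling_dose <- function(profile, bsa_m2, t1_min, t2_min, ...) {
  if (!is.finite(bsa_m2) || bsa_m2 <= 0) stop_cfg("bsa must be positive")
  cooling_dose(profile, t1_min, t2_min, ...) / bsa_m2
}

#' Reference full-protocol normalized cooling dose
#'
#' Closed-form normalized dose of the deterministic default protocol
#' (thermoneutral phase, one phase at shiver threshold + 6 degC, remainder at
#' shiver threshold + 3 degC) accumulated up to `endpoint_min`, for the
#' cohort-mean anthropometrics. Used to calibrate the phantom's per-decade
#' response slopes so that the configured endpoint FSF changes are realized
#' at the dose actually delivered by the default protocol.
#'
#' @param shiver_threshold,thermoneutral,duration_min,phase_min protocol
#'   parameters as in [simulate_cooling_protocol()].
#' @param endpoint_min endpoint time (min); default covers the default
#'   endpoint acquisition of a 21-acquisition session.
#' @param mass_kg,height_cm anthropometrics for the BSA denominator.
#' @return normalized cooling dose (degC min m^-2).
#' @export
reference_cooling_dose <- function(shiver_threshold = 15.6, thermoneutral = 32,
                                   duration_min = 60, phase_min = 8,
                                   endpoint_min = 64,
                                   mass_kg = 70.8, height_cm = 170.6) {
  endpoint_min <- min(endpoint_min, phase_min + duration_min)
  rel2 <- thermoneutral - (shiver_threshold + 6)
  rel3 <- thermoneutral - (shiver_threshold + 3)
  len2 <- max(0, min(endpoint_min, 2 * phase_min) - phase_min)
  len3 <- max(0, endpoint_min - 2 * phase_min)
  (rel2 * len2 + rel3 * len3) / dubois_bsa(mass_kg, height_cm)
}

#' Synchronize cooling and sensation logs to image acquisitions
#'
#' For each acquisition, computes the cumulative (normalized) cooling dose
#' from the start of the log to the scan midpoint and extracts the most
#' recent thermal sensation value at or before that time.
#'
#' @param profile a [cooling_profile()].
#' @param sensation a [sensation_log()].
#' @param acquisition_times_s scan start times (s), nondecreasing, within
#'   the log span.
#' @param bsa_m2 body surface area (m^2).
#' @param scan_duration_s scan duration (s); the reference instant is the
#'   scan midpoint.
#' @param ... passed to [cooling_dose()] (e.g. `temperature = "set"`).
#' @return data.frame of class `acquisition_log`: `acquisition`, `time_min`
#'   (midpoint), `cum_dose`, `cum_norm_dose`, `sensation`.
#' @export
sync_logs <- function(profile, sensation, acquisition_times_s, bsa_m2,
                      scan_duration_s = 115.7, ...) {
  if (!is.finite(bsa_m2) || bsa_m2 <= 0) stop_cfg("bsa must be positive")
  if (any(diff(acquisition_times_s) <= 0))
    stop_cfg("acquisitions must be strictly increasing in time")
  t0 <- min(profile$time_s)
  mids <- acquisition_times_s + scan_duration_s / 2
  if (any(acquisition_times_s < t0) || any(mids > max(profile$time_s)))
    stop_cfg("acquisition outside the log span")
  dose <- vapply(mids, function(m) {
    if (m / 60 <= t0 / 60 + 1e-12) 0
    else cooling_dose(profile, t0 / 60, m / 60, ...)
  }, numeric(1))
  sens <- vapply(mids, function(m) {
    i <- which(sensation$time_s <= m)
    if (!length(i)) stop_cfg("acquisition precedes the sensation log")
    sensation$sensation[max(i)]
  }, integer(1))
  structure(data.frame(acquisition = seq_along(mids), time_min = mids / 60,
                       cum_dose = dose, cum_norm_dose = dose / bsa_m2,
                       sensation = sens),
            class = c("acquisition_log", "data.frame"))
}
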