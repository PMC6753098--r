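# Digital neck/torso phantom for dynamic fat-water MRI of brown adipose
# tissue. The geometry (elliptical body cross-section, subcutaneous fat rind,
# muscle core, bilateral supraclavicular fat wedges) is schematic; only its
# statistical properties are anchored to measured tissue values.

#' Phantom configuration
#'
#' Collects the tunable parameters of the synthetic subject. Baseline BAT
#' fat-signal fractions are drawn from a decade-stratified mixture (uniform
#' within each 10-percentage-point decade) whose decade weights follow a
#' discretized Gaussian with mean solved so that the expected voxel mean
#' equals `bat_fsf_mean`; a floor on the weights guarantees that every decade
#' is populated. `bat_fsf_spread` is the s.d. (percentage points) of that
#' mixture envelope; setting it to 0 collapses all BAT voxels onto the mean.
#' `decade_changes_*` give the expected endpoint FSF change (percentage
#' points) of each initial-FSF decade after the full default cooling
#' protocol; per-dose slopes are these values divided by `reference_dose`.
#'
#' @param grid_dim grid dimensions (row, col, slice); 15 slices by default.
#' @param voxel_mm voxel size (mm).
#' @param bat_fsf_mean,bat_fsf_spread BAT baseline mixture mean / spread (%).
#' @param bat_decade_floor minimum relative decade weight of the BAT mixture.
#' @param sat_fsf_mean,sat_fsf_sd subcutaneous fat baseline Gaussian (%).
#' @param muscle_fsf_mean,muscle_fsf_sd muscle baseline Gaussian (%).
#' @param m0 proton signal amplitude inside the body (a.u.).
#' @param m0_texture_frac amplitude of the smooth multiplicative proton
#'   density / coil-sensitivity texture (fraction of `m0`).
#' @param field_map_amp_hz amplitude of the smooth true field map (Hz).
#' @param r2star_tissue named R2* per tissue (1/s): bat, sat, muscle.
#' @param r2star_var_hz smooth spatial R2* variation amplitude (1/s).
#' @param decade_changes_bat,decade_changes_sat,decade_changes_muscle
#'   endpoint FSF change per decade (pp at the reference dose), decades
#'   0-10% .. 90-100%.
#' @param reference_dose normalized cooling dose (degC min m^-2) at which
#'   `decade_changes_*` are realized; defaults to the dose accumulated by the
#'   default deterministic protocol at the default endpoint acquisition
#'   ([reference_cooling_dose()]).
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(grid_dim = c(64L, 64L, 15L),
                           voxel_mm = c(1.25, 1.25, 4),
                           bat_fsf_mean = 52.7, bat_fsf_spread = 26,
                           bat_decade_floor = 0.085,
                           sat_fsf_mean = 89.3, sat_fsf_sd = 6.7,
                           muscle_fsf_mean = 10, muscle_fsf_sd = 4,
                           m0 = 100, m0_texture_frac = 0.25,
                           field_map_amp_hz = 40,
                           r2star_tissue = c(bat = 45, sat = 35, muscle = 30),
                           r2star_var_hz = 5,
                           decade_changes_bat = c(6.7, 3.5, 1.5, 0, 0, 0,
                                                  -4, -7.5, -11, -14.4),
                           decade_changes_sat = c(0, 0, 0, 0, 0, 0, 0,
                                                  3.4, 0.87, -2.9),
                           decade_changes_muscle = c(2.7, rep(0, 9)),
                           reference_dose = NULL) {
  if (length(grid_dim) != 3L || any(grid_dim < 8 & c(TRUE, TRUE, FALSE)) ||
      any(grid_dim < 1))
    stop_cfg("grid_dim must be three positive sizes (in-plane >= 8)")
  check_scalar(bat_fsf_spread, "bat_fsf_spread", 0)
  check_scalar(sat_fsf_sd, "sat_fsf_sd", 0)
  check_scalar(muscle_fsf_sd, "muscle_fsf_sd", 0)
  check_scalar(bat_fsf_mean, "bat_fsf_mean", 0, 100)
  for (v in list(decade_changes_bat, decade_changes_sat, decade_changes_muscle))
    if (length(v) != 10L) stop_cfg("decade change vectors need 10 entries")
  structure(list(grid_dim = as.integer(grid_dim), voxel_mm = voxel_mm,
                 bat_fsf_mean = bat_fsf_mean, bat_fsf_spread = bat_fsf_spread,
                 bat_decade_floor = bat_decade_floor,
                 sat_fsf_mean = sat_fsf_mean, sat_fsf_sd = sat_fsf_sd,
                 muscle_fsf_mean = muscle_fsf_mean, muscle_fsf_sd = muscle_fsf_sd,
                 m0 = m0, m0_texture_frac = m0_texture_frac,
                 field_map_amp_hz = field_map_amp_hz,
                 r2star_tissue = r2star_tissue, r2star_var_hz = r2star_var_hz,
                 decade_changes = list(bat = decade_changes_bat,
                                       sat = decade_changes_sat,
                                       muscle = decade_changes_muscle),
                 reference_dose = reference_dose %||% reference_cooling_dose()),
            class = "phantom_config")
}

# Decade weights of the BAT baseline mixture: discretized Gaussian over the
# decade centers with a floor, envelope centre solved so the mixture mean
# hits the target.
bat_decade_weights <- function(mean_fsf, spread, floor_frac) {
  centers <- seq(5, 95, by = 10)
  weights_at <- function(ctr) {
    w <- stats::dnorm(centers, ctr, spread)
    w <- pmax(w / sum(w), floor_frac)
    w / sum(w)
  }
  f <- function(ctr) sum(weights_at(ctr) * centers) - mean_fsf
  ctr <- stats::uniroot(f, c(-100, 200), tol = 1e-10)$root
  weights_at(ctr)
}

#' Generate a synthetic subject
#'
#' Builds the labeled anatomy and the ground truth needed to simulate a full
#' dynamic fat-water MRI cooling study: baseline FSF per voxel, per-decade
#' cooling response slopes, proton amplitude, a smooth field map and R2*.
#'
#' @param config a [phantom_config()].
#' @param seed RNG seed; the phantom is bit-reproducible for a fixed seed.
#' @return list with elements `labels` (class `label_volume`) and `truth`
#'   (class `phantom_truth`; fields `baseline_fsf`, `m0`, `field_map_hz`,
#'   `r2star`, `slopes_per_dose`, `masks`, `reference_dose`, `config`).
#' @export
make_phantom <- function(config = phantom_config(), seed = 1L) {
  if (!inherits(config, "phantom_config")) stop_cfg("config must be a phantom_config")
  set.seed(seed)
  d <- config$grid_dim
  g <- coord_grids(d)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  rx <- 0.42 * d[1]; ry <- 0.34 * d[2]
  X <- (g$x - cx) / rx; Y <- (g$y - cy) / ry
  r2 <- X^2 + Y^2
  body <- r2 <= 1
  sat <- body & r2 >= 0.86^2
  bat <- body & !sat & r2 >= 0.30^2 & r2 <= 0.84^2 & X < -0.05 & abs(Y) > 0.10
  muscle <- body & !sat & !bat
  labels <- array(0L, d)
  labels[bat] <- 1L; labels[sat] <- 2L; labels[muscle] <- 3L

  # Baseline FSF values are drawn from the target tissue distributions and
  # then laid out with spatial coherence: values are rank-matched to a
  # smooth Gaussian random field, so lipid-rich and lipid-poor zones form
  # interspersed patches (as in real supraclavicular fat) rather than
  # voxel-wise salt-and-pepper noise. The marginal distribution (and hence
  # decade counts and the sample mean) is untouched by the rearrangement.
  baseline <- array(NA_real_, d)
  texture <- gauss_smooth3(array(stats::rnorm(prod(d)), d),
                           c(3.5, 3.5, min(2, (d[3] - 1) / 2)))
  place <- function(mask, values) {
    idx <- which(mask)
    baseline[idx[order(texture[idx])]] <<- sort(values)
  }
  alloc_counts <- function(w, n) {
    counts <- floor(w * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(w * n - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    counts
  }
  if (config$bat_fsf_spread == 0) {
    baseline[bat] <- config$bat_fsf_mean
  } else {
    w <- bat_decade_weights(config$bat_fsf_mean, config$bat_fsf_spread,
                            config$bat_decade_floor)
    # decade quotas are allocated slice-wise so that every analyzed slice
    # carries a representative share of each decade
    bat_arr <- array(bat, d)
    for (s in seq_len(d[3])) {
      msk <- array(FALSE, d)
      msk[, , s] <- bat_arr[, , s]
      n_s <- sum(msk)
      if (n_s == 0L) next
      decades <- rep.int(0:9, alloc_counts(w, n_s))
      place(msk, 10 * decades + 10 * stats::runif(n_s))
    }
  }
  place(sat, pmin(pmax(stats::rnorm(sum(sat), config$sat_fsf_mean,
                                    config$sat_fsf_sd), 0), 100))
  place(muscle, pmin(pmax(stats::rnorm(sum(muscle), config$muscle_fsf_mean,
                                       config$muscle_fsf_sd), 0), 100))

  # proton-density / coil-sensitivity modulation: smooth multiplicative
  # texture so anatomy-weighted magnitude images carry registration-usable
  # structure that is invariant to lipid change
  m0 <- array(0, d)
  pd_tex <- gauss_smooth3(array(stats::rnorm(prod(d)), d), c(1.5, 1.5, 0.75))
  pd_tex <- pd_tex / max(abs(pd_tex))
  m0[body] <- config$m0 * (1 + config$m0_texture_frac * pd_tex[body])
  Zn <- (g$z - (d[3] + 1) / 2) / max(1, (d[3] - 1) / 2)
  a <- stats::runif(4, -1, 1)
  fm <- config$field_map_amp_hz *
    (0.5 * a[1] + 0.6 * a[2] * X + 0.6 * a[3] * Y + 0.3 * a[4] * Zn +
       0.35 * sin(pi * X / 2) * sin(pi * Y / 2))
  field_map <- array(fm, d)
  r2star <- array(0, d)
  r2star[bat] <- config$r2star_tissue[["bat"]]
  r2star[sat] <- config$r2star_tissue[["sat"]]
  r2star[muscle] <- config$r2star_tissue[["muscle"]]
  bump <- array(config$r2star_var_hz * sin(pi * X) * cos(pi * Y / 2), d)
  r2star[body] <- pmax(r2star[body] + bump[body], 1)

  slopes <- array(0, d)
  ref <- config$reference_dose
  for (tis in c("bat", "sat", "muscle")) {
    msk <- switch(tis, bat = bat, sat = sat, muscle = muscle)
    dec <- pmin(floor(baseline[msk] / 10), 9) + 1L
    slopes[msk] <- config$decade_changes[[tis]][dec] / ref
  }

  masks <- list(bat = array(bat, d), bat_left = array(bat & Y < 0, d),
                bat_right = array(bat & Y > 0, d), sat = array(sat, d),
                muscle = array(muscle, d), body = array(body, d))
  label_vol <- structure(list(labels = labels, voxel_mm = config$voxel_mm,
                              n_slices = d[3],
                              codes = c(background = 0L, bat = 1L,
                                        sat = 2L, muscle = 3L)),
                         class = "label_volume")
  truth <- structure(list(baseline_fsf = baseline, m0 = m0,
                          field_map_hz = field_map, r2star = r2star,
                          slopes_per_dose = slopes, masks = masks,
                          reference_dose = ref, config = config, seed = seed),
                     class = "phantom_truth")
  list(labels = label_vol, truth = truth)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("Label volume %s (%s mm): %d BAT, %d SAT, %d muscle voxels\n",
              paste(dim(x$labels), collapse = "x"),
              paste(x$voxel_mm, collapse = "x"),
              sum(x$labels == 1L), sum(x$labels == 2L), sum(x$labels == 3L)))
  invisible(x)
}

#' Simulate decade-dependent FSF trajectories under cooling
#'
#' Evolves every tissue voxel's fat-signal fraction along the cooling
#' protocol: `FSF(t) = baseline + slope(decade(baseline)) * dose(t) + noise`,
#' clipped to [0, 100]. Slopes are per-decade ground-truth responses (high
#' initial-FSF decades lose lipid, low decades gain). Optional i.i.d. voxel
#' noise and a shared per-acquisition offset model physiological and scanner
#' fluctuations; both are zero at the baseline acquisition.
#'
#' @param truth `phantom_truth` from [make_phantom()].
#' @param dose_series per-acquisition normalized cooling dose, nondecreasing,
#'   starting at 0.
#' @param noise_sd i.i.d. per-voxel, per-acquisition noise s.d. (pp).
#' @param acq_noise_sd shared per-acquisition offset s.d. (pp).
#' @param seed RNG seed.
#' @return 4D array (grid x acquisition) of true FSF (%), `NA` outside the
#'   body; attribute `dose` stores the dose series.
#' @export
simulate_cooling_response <- function(truth, dose_series, noise_sd = 0,
                                      acq_noise_sd = 0, seed = 1L) {
  if (!inherits(truth, "phantom_truth")) stop_cfg("truth must be a phantom_truth")
  if (length(dose_series) < 1L || any(diff(dose_series) < -1e-9))
    stop_cfg("dose series must be nondecreasing")
  if (abs(dose_series[1]) > 1e-9) stop_cfg("dose series must start at 0")
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(acq_noise_sd, "acq_noise_sd", 0)
  set.seed(seed)
  d <- dim(truth$baseline_fsf)
  n_acq <- length(dose_series)
  out <- array(NA_real_, c(d, n_acq))
  body <- truth$masks$body
  base <- truth$baseline_fsf[body]
  slope <- truth$slopes_per_dose[body]
  shifts <- c(0, stats::rnorm(n_acq - 1L, 0, acq_noise_sd))
  for (a in seq_len(n_acq)) {
    eps <- if (noise_sd > 0 && a > 1L) stats::rnorm(length(base), 0, noise_sd) else 0
    v <- base + slope * dose_series[a] + eps + shifts[a]
    slab <- array(NA_real_, d)
    slab[body] <- pmin(pmax(v, 0), 100)
    out[, , , a] <- slab
  }
  attr(out, "dose") <- dose_series
  out
}

#' Apply inter-acquisition body motion to an echo series
#'
#' Warps all echoes of one acquisition with a single deformation (body motion
#' is common to the echoes of one scan) and returns the true field for
#' registration recovery tests. The field maps output coordinates to input
#' sampling positions: `warped(x) = original(x + u(x))`.
#'
#' @param series an `echo_series`.
#' @param motion list: `type = "none" | "translation" | "smooth"`, with
#'   `shift` (voxel triplet) for translations or `amplitude` (max in-plane
#'   displacement, voxels) for smooth random fields.
#' @param seed RNG seed for smooth fields.
#' @return list `series` (warped `echo_series`) and `field`
#'   (class `deformation_field`, array grid x 3, voxel units).
#' @export
apply_motion <- function(series, motion = list(type = "smooth", amplitude = 2),
                         seed = 1L) {
  if (!inherits(series, "echo_series")) stop_cfg("series must be an echo_series")
  d <- dim(series$data)[1:3]
  type <- motion$type %||% "smooth"
  u <- array(0, c(d, 3L))
  if (type == "translation") {
    shift <- rep_len(motion$shift %||% c(0, 0, 0), 3L)
    if (any(abs(shift) >= d)) stop_cfg("translation exceeds grid")
    for (c3 in 1:3) u[, , , c3] <- shift[c3]
  } else if (type == "smooth") {
    amp <- check_scalar(motion$amplitude %||% 2, "amplitude", 0)
    if (amp >= min(d[1:2]) / 4) stop_cfg("motion amplitude exceeds grid")
    if (amp > 0) {
      set.seed(seed)
      # body motion is mostly a bulk in-plane shift plus a smooth residual
      bulk <- c(stats::runif(2, -amp / 2, amp / 2), 0)
      comp_amp <- c(amp, amp, 0.15 * amp) / 2
      for (c3 in 1:3) {
        raw <- gauss_smooth3(array(stats::rnorm(prod(d)), d),
                             c(6, 6, min(2, (d[3] - 1) / 2)))
        m <- max(abs(raw))
        u[, , , c3] <- bulk[c3] + if (m > 0) raw / m * comp_amp[c3] else 0
      }
    }
  } else if (type != "none") stop_cfg("unknown motion type '%s'", type)
  field <- structure(u, class = "deformation_field")
  if (all(u == 0)) return(list(series = series, field = field))
  g <- coord_grids(d)
  xs <- g$x + as.vector(u[, , , 1])
  ys <- g$y + as.vector(u[, , , 2])
  zs <- g$z + as.vector(u[, , , 3])
  warped <- series$data
  for (k in seq_len(dim(series$data)[4])) {
    vol <- series$data[, , , k]
    re <- interp3(Re(vol), xs, ys, zs, fill = 0)
    im <- interp3(Im(vol), xs, ys, zs, fill = 0)
    warped[, , , k] <- array(complex(real = re, imaginary = im), d)
  }
  series$data <- warped
  list(series = series, field = field)
}

#' Simulate a personalized cooling protocol and sensation log
#'
#' Produces blanket water-temperature and thermal-sensation logs at a 30 s
#' cadence. The set temperature holds thermoneutral for one phase, steps to
#' 6 degC above the shiver threshold for one phase, then to 3 degC above the
#' shiver threshold for the remaining cold exposure. Actual water temperature
#' is the set temperature plus measurement noise. Thermal sensation declines
#' logistically with accumulated cooling dose from 50 (neutral) toward 0
#' (very cold), with seeded jitter, constrained to be nonincreasing.
#'
#' @param shiver_threshold shiver-threshold water temperature (degC).
#' @param thermoneutral thermoneutral blanket temperature (degC); must
#'   exceed `shiver_threshold + 6`.
#' @param duration_min cold-exposure duration (min) following the initial
#'   thermoneutral phase; 0 gives a single thermoneutral sample.
#' @param seed RNG seed.
#' @param phase_min phase length (min).
#' @param cadence_s logging cadence (s).
#' @param actual_noise_sd s.d. of actual-temperature noise (degC).
#' @param sensation_d0,sensation_k logistic midpoint and scale of the
#'   sensation decline, in cooling-dose units (degC min).
#' @return list with `profile` (class `cooling_profile`) and `sensation`
#'   (class `sensation_log`).
#' @export
simulate_cooling_protocol <- function(shiver_threshold, thermoneutral = 32,
                                      duration_min = 60, seed = 1L,
                                      phase_min = 8, cadence_s = 30,
                                      actual_noise_sd = 0.15,
                                      sensation_d0 = 250, sensation_k = 120) {
  check_scalar(shiver_threshold, "shiver_threshold")
  check_scalar(duration_min, "duration_min", 0)
  if (duration_min <= 0 && duration_min != 0) stop_cfg("nonpositive duration")
  if (thermoneutral <= shiver_threshold + 6)
    stop_cfg("thermoneutral must exceed shiver_threshold + 6")
  set.seed(seed)
  if (duration_min == 0) {
    profile <- cooling_profile(time_s = 0, set_temp_C = thermoneutral,
                               actual_temp_C = thermoneutral,
                               thermoneutral_C = thermoneutral)
    return(list(profile = profile,
                sensation = sensation_log(time_s = 0, sensation = 50L)))
  }
  total_s <- (phase_min + duration_min) * 60
  t_s <- seq(0, total_s, by = cadence_s)
  t_min <- t_s / 60
  set_temp <- ifelse(t_min < phase_min, thermoneutral,
                     ifelse(t_min < 2 * phase_min, shiver_threshold + 6,
                            shiver_threshold + 3))
  actual <- set_temp + stats::rnorm(length(t_s), 0, actual_noise_sd)
  actual[1] <- thermoneutral
  profile <- cooling_profile(time_s = t_s, set_temp_C = set_temp,
                             actual_temp_C = actual,
                             thermoneutral_C = thermoneutral)
  rel <- thermoneutral - set_temp
  dose <- c(0, cumsum((rel[-1] + rel[-length(rel)]) / 2 * diff(t_min)))
  raw <- 50 * (1 - stats::plogis((dose - sensation_d0) / sensation_k)) /
    (1 - stats::plogis(-sensation_d0 / sensation_k))
  s <- cummin(raw + stats::rnorm(length(raw), 0, 1))
  s <- as.integer(round(pmin(pmax(s, 0), 50)))
  s[1] <- 50L
  s <- cummin(s)
  list(profile = profile, sensation = sensation_log(time_s = t_s, sensation = s))
}
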