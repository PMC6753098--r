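# End-to-end orchestration: phantom -> echo synthesis (+motion) -> fat-water
# separation -> nonrigid registration -> ROI -> decade tracking -> cooling
# dose -> statistics, with an optional on-disk report (tidy CSVs, figures,
# run manifest). All randomness derives from one top-level seed.

#' Pipeline configuration
#'
#' Assembles the study conditions of a simulated dynamic cooling session.
#' Defaults reproduce the reference protocol: a 21-acquisition session (one
#' thermoneutral baseline plus 20 scans during cooling), 15-slice
#' 64 x 64 grid, personalized cooling from 32 degC to shiver threshold
#' + 3 degC, cohort-mean anthropometrics, SNR 50 echoes, ~2-voxel smooth
#' inter-acquisition motion.
#'
#' @param phantom a [phantom_config()]; its `reference_dose` is recalibrated
#'   to the dose the configured protocol delivers at the endpoint
#'   acquisition.
#' @param n_acquisitions total acquisitions (>= 2).
#' @param snr first-echo body signal-to-noise ratio of the synthesized
#'   echoes (signal amplitude over per-channel noise s.d.); `Inf` for
#'   noiseless data.
#' @param motion_amplitude max in-plane smooth motion amplitude (voxels);
#'   0 disables motion.
#' @param fsf_noise_sd,acq_noise_sd physiological FSF variability (pp):
#'   per-voxel i.i.d. and shared per-acquisition, respectively.
#' @param shiver_threshold,thermoneutral,duration_min,phase_min cooling
#'   protocol parameters ([simulate_cooling_protocol()]).
#' @param mass_kg,height_cm anthropometrics (JSON input in field studies).
#' @param scan_duration_s scan duration; acquisition reference time is the
#'   scan midpoint.
#' @param endpoint_acquisition cold-exposure endpoint acquisition index.
#' @param min_decade_voxels decade inclusion threshold.
#' @param slice_range analyzed slices (1-based inclusive).
#' @param fsf_threshold BAT threshold window used for decade tracking.
#' @param display_window BAT delineation display window.
#' @param background_threshold_frac background removal for FSF maps.
#' @param separation a [separation_options()].
#' @param demons a [demons_options()].
#' @param write_nifti also write echo/FSF NIfTI volumes in the report.
#' @return list of class `bat_pipeline_config`.
#' @export
bat_pipeline_config <- function(phantom = phantom_config(),
                                n_acquisitions = 21L, snr = 50,
                                motion_amplitude = 2,
                                fsf_noise_sd = 0.25, acq_noise_sd = 0.3,
                                shiver_threshold = 15.6, thermoneutral = 32,
                                duration_min = 60, phase_min = 8,
                                mass_kg = 70.8, height_cm = 170.6,
                                scan_duration_s = 115.7,
                                endpoint_acquisition = 20L,
                                min_decade_voxels = 60L,
                                slice_range = c(6L, 13L),
                                fsf_threshold = c(0, 100),
                                display_window = c(30, 80),
                                background_threshold_frac = 0.05,
                                separation = separation_options(),
                                demons = demons_options(),
                                write_nifti = FALSE) {
  if (n_acquisitions < 2L) stop_cfg("need at least 2 acquisitions")
  cfg <- list(phantom = phantom, n_acquisitions = as.integer(n_acquisitions),
              snr = snr, motion_amplitude = motion_amplitude,
              fsf_noise_sd = fsf_noise_sd, acq_noise_sd = acq_noise_sd,
              shiver_threshold = shiver_threshold, thermoneutral = thermoneutral,
              duration_min = duration_min, phase_min = phase_min,
              mass_kg = mass_kg, height_cm = height_cm,
              scan_duration_s = scan_duration_s,
              endpoint_acquisition = as.integer(endpoint_acquisition),
              min_decade_voxels = as.integer(min_decade_voxels),
              slice_range = as.integer(slice_range),
              fsf_threshold = fsf_threshold, display_window = display_window,
              background_threshold_frac = background_threshold_frac,
              separation = separation, demons = demons,
              write_nifti = isTRUE(write_nifti))
  class(cfg) <- "bat_pipeline_config"
  cfg
}

# Acquisition start times (s): baseline during the thermoneutral phase,
# the rest spread over the cooling period.
acquisition_times <- function(cfg) {
  total_s <- (cfg$phase_min + cfg$duration_min) * 60
  t1 <- max(0, cfg$phase_min * 60 / 2 - cfg$scan_duration_s / 2)
  n <- cfg$n_acquisitions
  first_cold <- (cfg$phase_min + 2) * 60
  last <- total_s - cfg$scan_duration_s - 30
  if (n == 2L) return(c(t1, last))
  c(t1, seq(first_cold, last, length.out = n - 1L))
}

#' Run the full analysis pipeline on a synthetic subject
#'
#' Executes every stage end to end: generates the phantom and its cooling
#' protocol, simulates decade-dependent FSF dynamics at the delivered dose,
#' synthesizes noisy multi-echo volumes with inter-acquisition motion,
#' drops leading train echoes, separates fat and water, registers all
#' acquisitions to the thermoneutral baseline (validated with fiducials),
#' builds eroded bilateral tissue ROIs, tracks FSF decades, synchronizes the
#' cooling dose and thermal sensation, and computes endpoint comparisons and
#' decade-wise Spearman correlations. If `outdir` is given, tidy CSV tables,
#' figures and a run manifest are written there.
#'
#' @param config a [bat_pipeline_config()], or a path to a YAML/JSON file of
#'   `bat_pipeline_config()` arguments.
#' @param seed top-level seed; all stage seeds derive from it.
#' @param outdir optional report directory.
#' @param verbose print stage progress.
#' @return object of class `bat_run` (see Details) with elements `config`,
#'   `truth`, `dose_table`, `decades` (per-tissue summaries), `endpoint`,
#'   `thresholds`, `correlations`, `registration`, `recovered`, `manifest`.
#' @export
run_pipeline <- function(config = bat_pipeline_config(), seed = 1L,
                         outdir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- load_pipeline_config(config)
  if (!inherits(config, "bat_pipeline_config")) stop_cfg("invalid config")
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_cfg("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  acq_t <- acquisition_times(config)
  n_acq <- config$n_acquisitions
  endpoint <- min(config$endpoint_acquisition, n_acq)
  if (endpoint < config$endpoint_acquisition)
    warning(sprintf("series shorter than endpoint acquisition %d; using %d",
                    config$endpoint_acquisition, endpoint))

  # calibrate the phantom response to the dose delivered at the endpoint
  bsa <- dubois_bsa(config$mass_kg, config$height_cm)
  mid_end_min <- (acq_t[endpoint] + config$scan_duration_s / 2) / 60
  pcfg <- config$phantom
  pcfg$reference_dose <- reference_cooling_dose(
    config$shiver_threshold, config$thermoneutral, config$duration_min,
    config$phase_min, endpoint_min = mid_end_min,
    mass_kg = config$mass_kg, height_cm = config$height_cm)

  say("phantom")
  ph <- stage("phantom", make_phantom(pcfg, derive_seed(seed, 1L)))
  truth <- ph$truth

  say("cooling protocol")
  proto <- stage("protocol", simulate_cooling_protocol(
    config$shiver_threshold, config$thermoneutral, config$duration_min,
    seed = derive_seed(seed, 2L), phase_min = config$phase_min))
  dose_table <- stage("sync", sync_logs(proto$profile, proto$sensation,
                                        acq_t, bsa,
                                        scan_duration_s = config$scan_duration_s))
  dose_t <- dose_table$cum_norm_dose
  dose_t[1] <- 0
  dose_t <- cummax(pmax(dose_t, 0))

  say("ground-truth FSF dynamics")
  truth_fsf <- stage("response", simulate_cooling_response(
    truth, dose_t, noise_sd = config$fsf_noise_sd,
    acq_noise_sd = config$acq_noise_sd, seed = derive_seed(seed, 3L)))

  sched <- build_echo_schedule()
  spectrum <- fat_spectrum()
  noise_sd <- if (is.finite(config$snr) && config$snr > 0)
    config$phantom$m0 / config$snr else 0

  fsf_maps <- vector("list", n_acq)
  anat <- vector("list", n_acq)   # species-sum magnitude: invariant to lipid change
  true_fields <- vector("list", n_acq)
  for (a in seq_len(n_acq)) {
    say("acquisition %d / %d", a, n_acq)
    fsf_a <- truth_fsf[, , , a]
    ser <- stage("synthesize", synthesize_echoes(
      fsf_a, truth$m0, truth$field_map_hz, truth$r2star, sched, spectrum,
      noise_sd = noise_sd, seed = derive_seed(seed, 10L + a),
      acquisition = a, timestamp_s = acq_t[a]))
    mo <- if (a == 1L || config$motion_amplitude <= 0) list(type = "none")
    else list(type = "smooth", amplitude = config$motion_amplitude)
    mv <- stage("motion", apply_motion(ser, mo, seed = derive_seed(seed, 100L + a)))
    true_fields[[a]] <- mv$field
    ser <- drop_leading_train_echoes(mv$series)
    sep <- stage("separate", separate_fat_water(ser, spectrum, config$separation))
    fsf_maps[[a]] <- stage("fsf", compute_fsf_map(sep, config$background_threshold_frac))
    anat[[a]] <- sep$total
    if (config$write_nifti && !is.null(outdir)) {
      dir.create(file.path(outdir, "nifti"), showWarnings = FALSE, recursive = TRUE)
      write_echo_series(mv$series, file.path(outdir, "nifti", sprintf("acq%02d", a)))
      write_fsf_volume(fsf_maps[[a]], file.path(outdir, "nifti", sprintf("acq%02d", a)))
    }
  }

  say("registration")
  fsf_reg <- fsf_maps
  reg_fields <- vector("list", n_acq)
  for (a in seq_len(n_acq)[-1]) {
    reg_fields[[a]] <- stage("register",
                             register_nonrigid(anat[[1L]], anat[[a]], config$demons))
    fsf_reg[[a]] <- stage("warp", warp_fsf(fsf_maps[[a]], reg_fields[[a]]))
  }

  # fiducial validation against the final cold-exposure acquisition
  fid_report <- NULL
  if (n_acq >= 2L) {
    fixed_pts <- stage("fiducials", pick_fiducials(anat[[1L]], truth$masks$body,
                                                   config$slice_range))
    pts <- as.matrix(fixed_pts[, c("row", "col", "slice")])
    before <- transform_points(true_fields[[n_acq]], pts, "to_warped")
    after <- transform_points(reg_fields[[n_acq]], before, "to_warped")
    as_fid <- function(m) fiducial_set(cbind(m[, 3], m[, 1], m[, 2]),
                                       labels = fixed_pts$label)
    fid_report <- validate_fiducials(as_fid(pts), as_fid(before), as_fid(after))
  }

  say("ROIs")
  fsf_tn <- fsf_reg[[1L]]
  sl <- config$slice_range
  seeds <- lapply(list(bat_left = truth$masks$bat_left,
                       bat_right = truth$masks$bat_right,
                       sat = truth$masks$sat, muscle = truth$masks$muscle),
                  function(m) mask_to_slices(m & fsf_tn$valid, sl[1], sl[2]))
  roi <- stage("roi", build_roi(fsf_tn, seeds, config$display_window))
  roi$masks <- lapply(roi$masks, erode_once)
  roi <- merge_roi_sides(roi)

  thr_list <- list("0-100" = c(0, 100), "40-100" = c(40, 100), "50-100" = c(50, 100))
  bat_main <- apply_fsf_threshold(fsf_tn, roi$masks$bat,
                                  config$fsf_threshold[1], config$fsf_threshold[2])

  say("decade tracking")
  track_masks <- list(bat = bat_main, sat = roi$masks$sat,
                      muscle = roi$masks$muscle)
  track_masks <- Filter(function(m) any(m), track_masks)
  tracks <- lapply(track_masks, function(m)
    stage("decades", assign_decades(fsf_tn, m)))
  decades <- lapply(tracks, summarize_decades, fsf_series = fsf_reg,
                    dose_series = dose_t,
                    sensation_series = dose_table$sensation,
                    min_voxels = config$min_decade_voxels)

  say("statistics")
  endpoint_tab <- do.call(rbind, lapply(names(decades), function(tis) {
    s <- decades[[tis]]
    tn <- s[s$acquisition == 1L, ]
    ce <- s[s$acquisition == endpoint, ]
    m <- merge(tn[, c("decade", "n_voxels", "mean_fsf")],
               ce[, c("decade", "mean_fsf")], by = "decade",
               suffixes = c("_tn", "_ce"))
    if (nrow(m) == 0L) return(NULL)
    data.frame(tissue = tis, decade = m$decade, n_voxels = m$n_voxels,
               mean_tn = m$mean_fsf_tn, mean_ce = m$mean_fsf_ce,
               change = m$mean_fsf_ce - m$mean_fsf_tn)
  }))

  # true decade-mean changes for the same voxels (generator reference)
  truth_tn <- truth_fsf[, , , 1L]
  truth_ce <- truth_fsf[, , , endpoint]
  tr_bat <- tracks$bat
  truth_changes <- vapply(split(seq_along(tr_bat$index), tr_bat$decade),
                          function(ii) mean(truth_ce[tr_bat$index[ii]] -
                                              truth_tn[tr_bat$index[ii]]),
                          numeric(1))

  roi_tab <- do.call(rbind, c(
    lapply(names(thr_list), function(nm) {
      m <- apply_fsf_threshold(fsf_tn, roi$masks$bat, thr_list[[nm]][1], thr_list[[nm]][2])
      roi_means("bat", nm, m, fsf_tn, fsf_reg[[endpoint]], seed)
    }),
    list(roi_means("sat", "0-100", roi$masks$sat, fsf_tn, fsf_reg[[endpoint]], seed),
         roi_means("muscle", "0-100", roi$masks$muscle, fsf_tn, fsf_reg[[endpoint]], seed))))

  cor_tab <- do.call(rbind, lapply(names(decades), function(tis) {
    s <- decades[[tis]]
    do.call(rbind, lapply(split(s, s$decade), function(sd_) {
      if (nrow(sd_) < 3L) return(NULL)
      r1 <- try(spearman_rho(sd_$norm_dose, sd_$mean_fsf), silent = TRUE)
      r2 <- try(spearman_rho(sd_$sensation, sd_$mean_fsf), silent = TRUE)
      data.frame(tissue = tis, decade = sd_$decade[1],
                 rho_dose = if (inherits(r1, "try-error")) NA_real_ else r1$estimate,
                 p_dose = if (inherits(r1, "try-error")) NA_real_ else r1$p_value,
                 rho_sensation = if (inherits(r2, "try-error")) NA_real_ else r2$estimate,
                 p_sensation = if (inherits(r2, "try-error")) NA_real_ else r2$p_value)
    }))
  }))

  run <- structure(list(
    config = config, seed = seed, bsa_m2 = bsa,
    acquisition_times_s = acq_t, dose_table = dose_table,
    reference_dose = pcfg$reference_dose,
    truth = list(decade_changes = truth_changes,
                 config_changes = pcfg$decade_changes,
                 reference_dose = pcfg$reference_dose),
    roi = roi, tracks = tracks, decades = decades,
    endpoint_acquisition = endpoint, endpoint = endpoint_tab,
    thresholds = roi_tab, correlations = cor_tab,
    registration = fid_report,
    fsf_tn = fsf_tn), class = "bat_run")

  if (!is.null(outdir)) run$manifest <- write_run_report(run, outdir)
  run
}

# Voxel-level TN/CE means and bootstrap CI of the mean change for one ROI.
roi_means <- function(tissue, window, mask, fsf_tn, fsf_ce, seed) {
  v1 <- fsf_tn$fsf[mask]
  v2 <- fsf_ce$fsf[mask]
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) < 2L)
    return(data.frame(tissue = tissue, window = window, n_voxels = sum(ok),
                      mean_tn = NA_real_, mean_ce = NA_real_,
                      change = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_))
  ci <- bootstrap_ci_mean_diff(v2[ok], v1[ok], seed = derive_seed(seed, 999L))
  data.frame(tissue = tissue, window = window, n_voxels = sum(ok),
             mean_tn = mean(v1[ok]), mean_ce = mean(v2[ok]),
             change = mean(v2[ok] - v1[ok]),
             ci_lo = ci$ci[1], ci_hi = ci$ci[2])
}

# Deterministic fiducial selection: strongest in-plane gradient magnitude
# on a spread of analyzed slices, with a minimum in-plane separation.
pick_fiducials <- function(vol, body, slice_range, n_points = 9L) {
  d <- dim(vol)
  slices <- unique(round(seq(slice_range[1], slice_range[2], length.out = 4L)))
  g <- gradient3(vol)
  gm <- sqrt(g[[1]]^2 + g[[2]]^2)
  gm[!body] <- 0
  pts <- NULL
  per_slice <- ceiling(n_points / length(slices))
  for (s in slices) {
    sl <- gm[, , s]
    ord <- order(sl, decreasing = TRUE)
    chosen <- NULL
    for (o in ord) {
      rc <- c((o - 1) %% d[1] + 1, (o - 1) %/% d[1] + 1)
      if (sl[o] <= 0) break
      if (is.null(chosen) ||
          all(sqrt(colSums((t(chosen) - rc)^2)) >= 8)) {
        chosen <- rbind(chosen, rc)
        if (nrow(chosen) >= per_slice) break
      }
    }
    if (!is.null(chosen))
      pts <- rbind(pts, cbind(chosen, slice = s))
  }
  pts <- pts[seq_len(min(n_points, nrow(pts))), , drop = FALSE]
  data.frame(label = paste0("F", seq_len(nrow(pts))),
             row = pts[, 1], col = pts[, 2], slice = pts[, 3])
}

load_pipeline_config <- function(path) {
  args <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_cfg("yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  phantom_args <- args$phantom %||% list()
  args$phantom <- do.call(phantom_config, phantom_args)
  do.call(bat_pipeline_config, args)
}

#' @export
print.bat_run <- function(x, ...) {
  cat(sprintf("BAT cooling run: %d acquisitions, endpoint %d, seed %d\n",
              x$config$n_acquisitions, x$endpoint_acquisition, x$seed))
  cat(sprintf("  normalized dose at endpoint: %.1f degC min m^-2 (BSA %.2f m^2)\n",
              x$dose_table$cum_norm_dose[x$endpoint_acquisition], x$bsa_m2))
  if (!is.null(x$registration))
    cat(sprintf("  fiducial median error %.2f -> %.2f px\n",
                attr(x$registration, "median_before"),
                attr(x$registration, "median_after")))
  bat <- x$endpoint[x$endpoint$tissue == "bat", ]
  cat("  BAT decade endpoint changes (pp):\n")
  cat(sprintf("    %s\n", paste(sprintf("%d:%+.1f", bat$decade, bat$change),
                                collapse = " ")))
  invisible(x)
}

#' @export
summary.bat_run <- function(object, ...) {
  print(object)
  cat("\nROI threshold comparison:\n")
  print(object$thresholds, row.names = FALSE, digits = 3)
  cat("\nSpearman correlations by decade:\n")
  print(object$correlations, row.names = FALSE, digits = 2)
  invisible(object)
}

# Write the tidy report: CSV tables, figures, manifest with file hashes.
write_run_report <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    paths[[length(paths) + 1L]] <<- p
    p
  }
  for (tis in names(run$decades)) {
    s <- as.data.frame(run$decades[[tis]])
    s$tissue <- rep(tis, nrow(s))
    wcsv(s[, c("acquisition", "tissue", "decade", "n_voxels", "mean_fsf",
               "norm_dose", "sensation")],
         sprintf("decades_%s.csv", tis))
  }
  wcsv(run$dose_table, "dose_table.csv")
  wcsv(run$endpoint, "endpoint_changes.csv")
  wcsv(run$thresholds, "threshold_comparison.csv")
  wcsv(run$correlations, "correlations.csv")
  if (!is.null(run$registration)) wcsv(run$registration, "registration_report.csv")

  pdf_path <- file.path(outdir, "figures.pdf")
  grDevices::pdf(pdf_path, width = 7, height = 5)
  tryCatch({
    plot_threshold_comparison(run)
    plot_decade_endpoints(run)
    plot_decade_dose_correlation(run)
    plot_decade_sensation_correlation(run)
  }, finally = grDevices::dev.off())
  paths <- c(paths, pdf_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("batlipid")),
    r_version = R.version.string,
    seed = run$seed,
    config = serialize_config(run$config),
    files = lapply(stats::setNames(paths, basename(paths)),
                   function(p) unname(tools::md5sum(p))))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  manifest
}

serialize_config <- function(cfg) {
  drop <- function(x) if (is.list(x)) lapply(unclass(x), drop) else x
  drop(cfg)
}
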