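# Complex multi-echo gradient-echo signal model shared by the phantom
# generator and the fat-water separation fit:
#   S(TE) = (W + F * c(TE)) * exp(i 2 pi psi TE) * exp(-R2* TE)
# with c(TE) the multi-peak fat modulation, psi the field-map offset (Hz)
# and a common R2* (1/s) for both species. TE in seconds.

# K x V complex signal matrix for vectors W, F, psi (Hz), r2s (1/s).
fw_signal <- function(W, F, psi, r2s, te_s, spectrum) {
  ck <- fat_modulation(spectrum, te_s)
  base <- outer(te_s, psi, function(t, p) exp(1i * 2 * pi * p * t)) *
    exp(-outer(te_s, r2s))
  (matrix(W, nrow = length(te_s), ncol = length(W), byrow = TRUE) +
     ck * matrix(F, nrow = length(te_s), ncol = length(F), byrow = TRUE)) * base
}

#' Construct an echo series
#'
#' Low-level constructor bundling a complex multi-echo voxel grid with its
#' echo schedule. `data` is a 4D complex array (row, col, slice, echo).
#'
#' @param data complex 4D array.
#' @param schedule an [build_echo_schedule()] object matching dim 4.
#' @param acquisition acquisition index (1 = thermoneutral baseline).
#' @param timestamp_s acquisition start time in seconds from protocol start.
#' @param voxel_mm voxel size triplet (mm).
#' @return object of class `echo_series`.
#' @export
echo_series <- function(data, schedule, acquisition = 1L, timestamp_s = 0,
                        voxel_mm = c(1.25, 1.25, 4)) {
  if (length(dim(data)) != 4L) stop_cfg("echo data must be a 4D array")
  if (dim(data)[4] != length(schedule$te_ms))
    stop_cfg("echo count (%d) does not match schedule (%d)",
             dim(data)[4], length(schedule$te_ms))
  if (!all(is.finite(Re(data))) || !all(is.finite(Im(data))))
    stop_cfg("echo data must be finite")
  structure(list(data = data, schedule = schedule,
                 acquisition = as.integer(acquisition),
                 timestamp_s = timestamp_s, voxel_mm = voxel_mm),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Echo series: %d x %d x %d grid, %d echoes (acquisition %d, t = %.1f s)\n",
              d[1], d[2], d[3], d[4], x$acquisition, x$timestamp_s))
  invisible(x)
}

#' Synthesize a complex multi-echo series from tissue parameter maps
#'
#' Generates the complex gradient-echo signal of every voxel from its
#' fat-signal fraction, proton signal amplitude, field-map offset and R2*,
#' using the multi-peak fat model, and adds i.i.d. complex Gaussian noise.
#' Water and fat amplitudes are `W = m0 (1 - FSF/100)` and `F = m0 FSF/100`,
#' so `F / (F + W)` reproduces the input fat fraction exactly.
#'
#' @param fsf FSF array (%), `NA` allowed only where `m0 == 0`.
#' @param m0 proton signal amplitude array (arbitrary units, >= 0).
#' @param field_map_hz field-map offset array (Hz).
#' @param r2star R2* array (1/s).
#' @param schedule echo schedule ([build_echo_schedule()]).
#' @param spectrum fat spectrum ([fat_spectrum()]).
#' @param noise_sd complex noise s.d. per real/imaginary channel.
#' @param seed RNG seed for the noise draw.
#' @param acquisition,timestamp_s,voxel_mm metadata stored on the series.
#' @return an `echo_series`.
#' @export
synthesize_echoes <- function(fsf, m0, field_map_hz, r2star, schedule,
                              spectrum = fat_spectrum(), noise_sd = 0,
                              seed = 1L, acquisition = 1L, timestamp_s = 0,
                              voxel_mm = c(1.25, 1.25, 4)) {
  check_scalar(noise_sd, "noise_sd", 0)
  d <- dim(fsf)
  if (is.null(d) || length(d) != 3L) stop_cfg("fsf must be a 3D array")
  active <- m0 > 0
  f <- fsf
  f[!active] <- 0
  if (anyNA(f[active])) stop_cfg("FSF is NA on voxels with signal")
  if (any(f < 0 | f > 100)) stop_cfg("FSF outside [0, 100]")
  te_s <- schedule$te_ms / 1000
  frac <- as.vector(f) / 100
  W <- as.vector(m0) * (1 - frac)
  Fa <- as.vector(m0) * frac
  S <- fw_signal(W, Fa, as.vector(field_map_hz), as.vector(r2star), te_s, spectrum)
  if (noise_sd > 0) {
    set.seed(seed)
    S <- S + complex(real = rnorm(length(S), 0, noise_sd),
                     imaginary = rnorm(length(S), 0, noise_sd))
  }
  data <- array(t(S), dim = c(d, length(te_s)))
  echo_series(data, schedule, acquisition = acquisition,
              timestamp_s = timestamp_s, voxel_mm = voxel_mm)
}

#' Construct an FSF volume
#'
#' Bundles a per-voxel fat-signal-fraction map (%) with its validity mask.
#' Invalid voxels (background, failed fits, out-of-range separation results)
#' carry `NA`, never a silent zero.
#'
#' @param fsf 3D array of FSF values (%); `NA` where invalid.
#' @param valid logical 3D array marking valid voxels.
#' @param voxel_mm voxel size triplet (mm).
#' @return object of class `fsf_volume`.
#' @export
fsf_volume <- function(fsf, valid = !is.na(fsf), voxel_mm = c(1.25, 1.25, 4)) {
  if (!identical(dim(fsf), dim(valid))) stop_cfg("fsf/valid shape mismatch")
  if (any(fsf[valid] < 0 | fsf[valid] > 100, na.rm = TRUE))
    stop_cfg("valid FSF values must lie in [0, 100]")
  fsf[!valid] <- NA_real_
  structure(list(fsf = fsf, valid = valid, voxel_mm = voxel_mm),
            class = "fsf_volume")
}

#' @export
print.fsf_volume <- function(x, ...) {
  d <- dim(x$fsf)
  cat(sprintf("FSF volume %d x %d x %d: %d valid voxels (%.1f%%), mean %.1f%%\n",
              d[1], d[2], d[3], sum(x$valid), 100 * mean(x$valid),
              mean(x$fsf[x$valid])))
  invisible(x)
}
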