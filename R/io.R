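# External interfaces: NIfTI volumes (magnitude + phase pairs per echo with
# a JSON sidecar carrying the echo schedule), temperature/sensation CSV
# logs, fiducial CSVs and tidy decade-summary CSVs.

#' Write an echo series as NIfTI magnitude/phase pairs
#'
#' Writes `<prefix>_mag.nii.gz` and `<prefix>_phase.nii.gz` (4D: space x
#' echo) plus `<prefix>.json` with echo times (ms), train indices,
#' acquisition index and timestamp.
#'
#' @param series an `echo_series`.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_echo_series <- function(series, prefix) {
  if (!inherits(series, "echo_series")) stop_cfg("series must be an echo_series")
  mag_f <- paste0(prefix, "_mag.nii.gz")
  ph_f <- paste0(prefix, "_phase.nii.gz")
  js_f <- paste0(prefix, ".json")
  pix <- series$voxel_mm
  RNifti::writeNifti(RNifti::asNifti(Mod(series$data), pixdim = pix), mag_f)
  RNifti::writeNifti(RNifti::asNifti(Arg(series$data), pixdim = pix), ph_f)
  side <- list(echo_times_ms = series$schedule$te_ms,
               train = series$schedule$train,
               n_trains = series$schedule$n_trains,
               acquisition = series$acquisition,
               timestamp_s = series$timestamp_s,
               voxel_mm = series$voxel_mm)
  jsonlite::write_json(side, js_f, auto_unbox = TRUE, digits = NA)
  invisible(c(mag_f, ph_f, js_f))
}

#' Read an echo series written by [write_echo_series()]
#'
#' @param prefix path prefix used at write time.
#' @return an `echo_series`.
#' @export
read_echo_series <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  mag <- as.array(RNifti::readNifti(paste0(prefix, "_mag.nii.gz")))
  ph <- as.array(RNifti::readNifti(paste0(prefix, "_phase.nii.gz")))
  sched <- structure(list(te_ms = side$echo_times_ms,
                          train = as.integer(side$train),
                          n_trains = as.integer(side$n_trains)),
                     class = "echo_schedule")
  echo_series(array(complex(modulus = mag, argument = ph), dim(mag)), sched,
              acquisition = side$acquisition, timestamp_s = side$timestamp_s,
              voxel_mm = side$voxel_mm)
}

#' Write an FSF volume (values + validity mask) as NIfTI
#'
#' @param fsf an [fsf_volume()].
#' @param prefix output path prefix; writes `<prefix>_fsf.nii.gz` (invalid
#'   voxels encoded as -1) and `<prefix>_valid.nii.gz`.
#' @return invisibly, the file paths.
#' @export
write_fsf_volume <- function(fsf, prefix) {
  vals <- fsf$fsf
  vals[!fsf$valid] <- -1
  f1 <- paste0(prefix, "_fsf.nii.gz"); f2 <- paste0(prefix, "_valid.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vals, pixdim = fsf$voxel_mm), f1)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(fsf$valid), dim(vals)),
                                     pixdim = fsf$voxel_mm), f2)
  invisible(c(f1, f2))
}

#' Read an FSF volume written by [write_fsf_volume()]
#' @param prefix path prefix used at write time.
#' @return an [fsf_volume()].
#' @export
read_fsf_volume <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, "_fsf.nii.gz"))
  vals <- as.array(img)
  vals <- array(as.vector(vals), dim(vals))
  vraw <- as.array(RNifti::readNifti(paste0(prefix, "_valid.nii.gz")))
  valid <- array(as.vector(vraw) > 0.5, dim(vraw))
  vals[!valid] <- NA_real_
  pd <- attr(img, "pixdim") %||% c(1.25, 1.25, 4)
  fsf_volume(vals, valid, voxel_mm = pd[1:3])
}

#' Write / read fiducial CSV (`label,slice,row,col`)
#' @param fid a [fiducial_set()].
#' @param path CSV path.
#' @export
write_fiducials <- function(fid, path) {
  utils::write.csv(as.data.frame(fid)[, c("label", "slice", "row", "col")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fiducials
#' @export
read_fiducials <- function(path) {
  df <- utils::read.csv(path)
  fiducial_set(df[, c("slice", "row", "col")], labels = df$label)
}

#' Write cooling / sensation logs as CSV
#'
#' Temperature log columns: `time_s,set_temp_C,actual_temp_C`; sensation
#' log columns: `time_s,sensation`.
#'
#' @param profile a [cooling_profile()].
#' @param sensation a [sensation_log()].
#' @param temp_path,sens_path output CSV paths.
#' @export
write_cooling_logs <- function(profile, sensation, temp_path, sens_path) {
  utils::write.csv(as.data.frame(profile), temp_path, row.names = FALSE)
  utils::write.csv(as.data.frame(sensation), sens_path, row.names = FALSE)
  invisible(c(temp_path, sens_path))
}

#' Read cooling / sensation CSV logs
#' @param temp_path,sens_path CSV paths as written by [write_cooling_logs()].
#' @param thermoneutral_C thermoneutral reference; defaults to the first
#'   set temperature.
#' @return list with `profile` and `sensation`.
#' @export
read_cooling_logs <- function(temp_path, sens_path, thermoneutral_C = NULL) {
  tp <- utils::read.csv(temp_path)
  sp <- utils::read.csv(sens_path)
  list(profile = cooling_profile(tp$time_s, tp$set_temp_C, tp$actual_temp_C,
                                 thermoneutral_C %||% tp$set_temp_C[1]),
       sensation = sensation_log(sp$time_s, sp$sensation))
}
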