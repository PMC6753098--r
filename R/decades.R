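# FSF decade tracking: voxels are binned by their thermoneutral FSF into
# ten decades {0-10%}, ..., {90-100%} and keep that identity for every
# later acquisition, so differential lipid loss/gain of initially lipid-rich
# and lipid-poor tissue can be followed directly.

#' Assign ROI voxels to FSF decades at thermoneutrality
#'
#' Bins each ROI voxel by its thermoneutral FSF into decade
#' `floor(FSF / 10)`; bins are half-open `[10 d, 10 d + 10)` except the top
#' bin, which is closed so FSF = 100 belongs to the 90-100% decade. The
#' assignment is frozen: the same voxels define each decade at every later
#' acquisition.
#'
#' @param fsf_tn thermoneutral [fsf_volume()] (registration reference).
#' @param mask logical ROI mask; every mask voxel must be valid in `fsf_tn`.
#' @return object of class `decade_track`: voxel indices, per-voxel decade
#'   (0, 10, ..., 90 label = lower bin edge), per-decade counts, grid dim.
#' @export
assign_decades <- function(fsf_tn, mask) {
  if (!inherits(fsf_tn, "fsf_volume")) stop_cfg("fsf_tn must be an fsf_volume")
  if (!identical(dim(mask), dim(fsf_tn$fsf))) stop_cfg("mask shape mismatch")
  idx <- which(mask)
  if (!length(idx)) stop_cfg("empty ROI mask")
  if (any(!fsf_tn$valid[idx]))
    stop_cfg("ROI contains voxels invalid in the thermoneutral FSF map")
  vals <- fsf_tn$fsf[idx]
  dec <- pmin(floor(vals / 10), 9L)
  counts <- tabulate(dec + 1L, nbins = 10L)
  names(counts) <- seq(0, 90, by = 10)
  structure(list(index = idx, decade = as.integer(10L * dec),
                 counts = counts, dim = dim(fsf_tn$fsf),
                 baseline = vals),
            class = "decade_track")
}

#' @export
print.decade_track <- function(x, ...) {
  cat(sprintf("Decade track: %d voxels\n", length(x$index)))
  print(x$counts)
  invisible(x)
}

#' Summarize tracked decades across acquisitions
#'
#' Computes the mean FSF of every included decade at every acquisition,
#' together with the synchronized normalized cooling dose and thermal
#' sensation. Decades with fewer than `min_voxels` member voxels at
#' assignment are excluded entirely (unstable means); decade membership
#' never changes across acquisitions.
#'
#' @param track a [assign_decades()] result.
#' @param fsf_series list of registered [fsf_volume()]s, one per
#'   acquisition (acquisition 1 = thermoneutral reference).
#' @param dose_series per-acquisition cumulative normalized cooling dose
#'   (same length as `fsf_series`), or `NULL`.
#' @param sensation_series per-acquisition thermal sensation, or `NULL`.
#' @param min_voxels inclusion threshold: decades with
#'   `count < min_voxels` are dropped (strict inequality, so a 60-voxel
#'   decade is included under the default).
#' @return data.frame of class `decade_summary`: one row per
#'   (acquisition, decade) with `n_voxels` (valid voxels that acquisition),
#'   `mean_fsf`, `norm_dose`, `sensation`.
#' @export
summarize_decades <- function(track, fsf_series, dose_series = NULL,
                              sensation_series = NULL, min_voxels = 60L) {
  if (!inherits(track, "decade_track")) stop_cfg("track must be a decade_track")
  n_acq <- length(fsf_series)
  for (fv in fsf_series)
    if (!identical(dim(fv$fsf), track$dim))
      stop_cfg("FSF series not registered to the tracking grid")
  if (!is.null(dose_series) && length(dose_series) != n_acq)
    stop_cfg("dose series length mismatch")
  if (!is.null(sensation_series) && length(sensation_series) != n_acq)
    stop_cfg("sensation series length mismatch")
  included <- as.integer(names(track$counts))[track$counts >= min_voxels]
  rows <- vector("list", n_acq * length(included))
  i <- 0L
  for (a in seq_len(n_acq)) {
    vals_a <- fsf_series[[a]]$fsf[track$index]
    for (dec in included) {
      sel <- track$decade == dec
      v <- vals_a[sel]
      i <- i + 1L
      rows[[i]] <- data.frame(acquisition = a, decade = dec,
                              n_voxels = sum(!is.na(v)),
                              mean_fsf = mean(v, na.rm = TRUE),
                              norm_dose = if (is.null(dose_series)) NA_real_ else dose_series[a],
                              sensation = if (is.null(sensation_series)) NA_real_ else sensation_series[a])
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(acquisition = integer(0), decade = integer(0),
                      n_voxels = integer(0), mean_fsf = numeric(0),
                      norm_dose = numeric(0), sensation = numeric(0))
  attr(out, "min_voxels") <- min_voxels
  attr(out, "excluded") <- setdiff(as.integer(names(track$counts)), included)
  class(out) <- c("decade_summary", "data.frame")
  out
}

#' @export
print.decade_summary <- function(x, ...) {
  cat(sprintf("Decade summary: %d acquisitions x %d decades (min voxels %d)\n",
              length(unique(x$acquisition)), length(unique(x$decade)),
              attr(x, "min_voxels")))
  if (length(attr(x, "excluded")))
    cat("  excluded decades:", paste(attr(x, "excluded"), collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat(sprintf("  ... %d more rows\n", nrow(x) - 12))
  invisible(x)
}

#' Bootstrap sizing of the minimal stable ROI
#'
#' Determines how many voxels a region must contain for its mean FSF to be
#' estimated within a required precision: for increasing subsample size `n`,
#' draws `n_boot` bootstrap subsamples from the supplied voxel-wise FSF
#' population, forms the 95% percentile interval of the subsample mean, and
#' returns the smallest `n` whose half-width does not exceed
#' `half_width_limit` percentage points.
#'
#' @param values voxel-wise FSF population (at least 100 values).
#' @param half_width_limit precision requirement (pp), positive.
#' @param n_boot bootstrap resamples per candidate size.
#' @param seed RNG seed.
#' @param level interval coverage.
#' @param query_n optional additional size at which to report the
#'   half-width.
#' @return list: `min_n`, `half_width_at_min`, and (if `query_n` given)
#'   `query_half_width`.
#' @export
bootstrap_min_roi_size <- function(values, half_width_limit = 5, n_boot = 1000L,
                                   seed = 1L, level = 0.95, query_n = NULL) {
  if (length(values) < 100L) stop_cfg("need at least 100 population values")
  if (!is.finite(half_width_limit) || half_width_limit <= 0)
    stop_cfg("half_width_limit must be positive")
  set.seed(seed)
  alpha <- (1 - level) / 2
  hw <- function(n) {
    means <- colMeans(matrix(sample(values, n * n_boot, replace = TRUE),
                             nrow = n))
    q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
    (q[2] - q[1]) / 2
  }
  min_n <- NA_integer_
  hw_min <- NA_real_
  for (n in 2:length(values)) {
    h <- hw(n)
    if (h <= half_width_limit) { min_n <- n; hw_min <- h; break }
  }
  out <- list(min_n = min_n, half_width_at_min = hw_min)
  if (!is.null(query_n)) out$query_half_width <- hw(as.integer(query_n))
  out
}
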