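# Intensity-driven nonrigid registration. A multiresolution demons scheme
# recovers a dense displacement field from water-magnitude volumes; the
# field is then applied to FSF maps so that voxels can be tracked across
# acquisitions. Displacement fields use the pull-back convention
# warped(x) = moving(x + u(x)), in voxel units.

#' Demons registration options
#'
#' @param levels number of in-plane pyramid levels (coarsest factor
#'   `2^(levels-1)`).
#' @param iterations iterations per level, coarse to fine.
#' @param sigma_field Gaussian sigma (voxels) regularizing the accumulated
#'   field each iteration.
#' @param sigma_update Gaussian sigma (voxels) smoothing each force update.
#' @param sigma_z through-slice sigma (voxels); slices are thick, so motion
#'   is regularized less across slices.
#' @param step_cap maximum per-iteration displacement update (voxels).
#' @return list of class `demons_options`.
#' @export
demons_options <- function(levels = 3L, iterations = c(100L, 60L, 30L),
                           sigma_field = 1.5, sigma_update = 1.0,
                           sigma_z = 0.5, step_cap = 1.25) {
  structure(list(levels = as.integer(levels),
                 iterations = rep_len(as.integer(iterations), levels),
                 sigma_field = sigma_field, sigma_update = sigma_update,
                 sigma_z = sigma_z, step_cap = step_cap),
            class = "demons_options")
}

# Block-average in-plane downsampling (real volume).
down2 <- function(vol) {
  d <- dim(vol)
  n1 <- d[1] %/% 2L; n2 <- d[2] %/% 2L
  v <- vol[seq_len(2L * n1), seq_len(2L * n2), , drop = FALSE]
  a <- array(v, c(2L, n1, 2L, n2, d[3]))
  array(apply(a, c(2, 4, 5), mean), c(n1, n2, d[3]))
}

warp_array <- function(vol, u, fill = 0, clamp = TRUE) {
  d <- dim(vol)
  g <- coord_grids(d)
  array(interp3(vol, g$x + as.vector(u[, , , 1]), g$y + as.vector(u[, , , 2]),
                g$z + as.vector(u[, , , 3]), fill = fill, clamp = clamp), d)
}

demons_level <- function(Fv, Mv, u, iters, opt) {
  d <- dim(Fv)
  sig_up <- c(opt$sigma_update, opt$sigma_update, opt$sigma_z)
  sig_fl <- c(opt$sigma_field, opt$sigma_field, opt$sigma_z)
  gF <- gradient3(Fv)
  for (it in seq_len(iters)) {
    Mw <- warp_array(Mv, u)
    diff <- Fv - Mw
    gM <- gradient3(Mw)
    g1 <- (gF[[1]] + gM[[1]]) / 2
    g2 <- (gF[[2]] + gM[[2]]) / 2
    g3 <- (gF[[3]] + gM[[3]]) / 2
    den <- g1^2 + g2^2 + g3^2 + diff^2
    scl <- ifelse(den > 1e-9, diff / den, 0)
    v1 <- scl * g1; v2 <- scl * g2; v3 <- scl * g3
    nrm <- sqrt(v1^2 + v2^2 + v3^2)
    over <- nrm > opt$step_cap
    if (any(over)) {
      sc <- ifelse(over, opt$step_cap / nrm, 1)
      v1 <- v1 * sc; v2 <- v2 * sc; v3 <- v3 * sc
    }
    u[, , , 1] <- gauss_smooth3(u[, , , 1] + gauss_smooth3(v1, sig_up), sig_fl)
    u[, , , 2] <- gauss_smooth3(u[, , , 2] + gauss_smooth3(v2, sig_up), sig_fl)
    u[, , , 3] <- gauss_smooth3(u[, , , 3] + gauss_smooth3(v3, sig_up), sig_fl)
  }
  u
}

#' Nonrigid (demons) registration of two volumes
#'
#' Recovers a dense displacement field aligning `moving` to `fixed` with a
#' multiresolution diffusion-regularized demons scheme on intensity volumes
#' (typically water magnitude images). Deterministic for fixed options.
#'
#' @param fixed,moving 3D numeric arrays of identical shape.
#' @param options a [demons_options()].
#' @return a `deformation_field` (array grid x 3, voxel units) such that
#'   `moving(x + u(x))` matches `fixed(x)`.
#' @export
register_nonrigid <- function(fixed, moving, options = demons_options()) {
  if (!identical(dim(fixed), dim(moving))) stop_cfg("volume shape mismatch")
  if (length(dim(fixed)) != 3L) stop_cfg("volumes must be 3D")
  scale <- stats::quantile(abs(fixed), 0.99, names = FALSE)
  if (scale <= 0) scale <- 1
  Fv <- pmin(fixed / scale, 2)
  Mv <- pmin(moving / scale, 2)
  levels <- options$levels
  pyrF <- list(Fv); pyrM <- list(Mv)
  for (l in seq_len(levels - 1L)) {
    if (min(dim(pyrF[[l]])[1:2]) < 16L) { levels <- l; break }
    pyrF[[l + 1L]] <- down2(pyrF[[l]])
    pyrM[[l + 1L]] <- down2(pyrM[[l]])
  }
  u <- NULL
  for (l in rev(seq_len(levels))) {
    dl <- dim(pyrF[[l]])
    if (is.null(u)) {
      u <- array(0, c(dl, 3L))
    } else {
      uf <- array(0, c(dl, 3L))
      g <- coord_grids(dl)
      for (c3 in 1:3) {
        comp <- interp3(u[, , , c3], g$x / 2 + 0.25, g$y / 2 + 0.25, g$z,
                        clamp = TRUE)
        uf[, , , c3] <- array(comp, dl) * if (c3 < 3) 2 else 1
      }
      u <- uf
    }
    iters <- options$iterations[min(levels - l + 1L, length(options$iterations))]
    u <- demons_level(pyrF[[l]], pyrM[[l]], u, iters, options)
  }
  structure(u, class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x[, , , 1]^2 + x[, , , 2]^2 + x[, , , 3]^2)
  cat(sprintf("Deformation field %s: mean |u| %.3f, max |u| %.3f voxels\n",
              paste(dim(x)[1:3], collapse = "x"), mean(mag), max(mag)))
  invisible(x)
}

#' Warp an FSF map with a deformation field
#'
#' Resamples an FSF map along a displacement field using normalized linear
#' interpolation restricted to valid voxels; the validity mask itself is
#' warped with nearest-neighbour sampling. Out-of-grid samples become
#' invalid and interpolated values are re-clipped to [0, 100].
#'
#' @param fsf an [fsf_volume()].
#' @param field a `deformation_field` of matching shape.
#' @return the warped [fsf_volume()].
#' @export
warp_fsf <- function(fsf, field) {
  d <- dim(fsf$fsf)
  if (!identical(dim(field)[1:3], d)) stop_cfg("field/FSF shape mismatch")
  g <- coord_grids(d)
  xs <- g$x + as.vector(field[, , , 1])
  ys <- g$y + as.vector(field[, , , 2])
  zs <- g$z + as.vector(field[, , , 3])
  vnum <- fsf$fsf
  vnum[!fsf$valid] <- 0
  wgt <- array(as.numeric(fsf$valid), d)
  num <- interp3(vnum, xs, ys, zs, fill = 0)
  den <- interp3(wgt, xs, ys, zs, fill = 0)
  valid_nn <- nn3(array(fsf$valid, d), xs, ys, zs, fill = FALSE)
  valid <- array(as.logical(valid_nn) & den > 1e-6, d)
  vals <- array(NA_real_, d)
  vals[valid] <- pmin(pmax(num[valid] / den[valid], 0), 100)
  fsf_volume(vals, valid, voxel_mm = fsf$voxel_mm)
}

#' Map point coordinates through a deformation field
#'
#' With the pull-back convention `warped(x) = moving(x + u(x))`, a feature
#' at `q` in the moving image appears in the warped image at the point `x`
#' solving `x + u(x) = q`; `direction = "to_warped"` solves this by
#' fixed-point iteration. `direction = "to_moving"` evaluates `x + u(x)`.
#'
#' @param field a `deformation_field`.
#' @param points matrix with columns (row, col, slice), one point per row.
#' @param direction see description.
#' @param iters fixed-point iterations.
#' @return matrix of mapped points.
#' @export
transform_points <- function(field, points, direction = c("to_warped", "to_moving"),
                             iters = 20L) {
  direction <- match.arg(direction)
  points <- as.matrix(points)
  samp <- function(p) {
    cbind(interp3(field[, , , 1], p[, 1], p[, 2], p[, 3], clamp = TRUE),
          interp3(field[, , , 2], p[, 1], p[, 2], p[, 3], clamp = TRUE),
          interp3(field[, , , 3], p[, 1], p[, 2], p[, 3], clamp = TRUE))
  }
  if (direction == "to_moving") return(points + samp(points))
  x <- points
  for (i in seq_len(iters)) x <- points - samp(x)
  x
}

#' Fiducial set constructor
#'
#' @param points matrix or data.frame with columns (slice, row, col).
#' @param labels point labels.
#' @return data.frame of class `fiducial_set`.
#' @export
fiducial_set <- function(points, labels = NULL) {
  points <- as.data.frame(points)
  names(points) <- c("slice", "row", "col")
  points$label <- labels %||% paste0("P", seq_len(nrow(points)))
  structure(points[, c("label", "slice", "row", "col")],
            class = c("fiducial_set", "data.frame"))
}

#' Validate registration with fiducial (control point) distances
#'
#' Computes the in-plane Euclidean distance (pixels) of each control point
#' to its counterpart in the fixed image, before and after registration,
#' and summarizes the median and interquartile range.
#'
#' @param fixed,moving_before,moving_after [fiducial_set()]s with matching
#'   labels.
#' @return object of class `registration_report`: data.frame of per-point
#'   distances plus `median_before`, `median_after`, `iqr_before`,
#'   `iqr_after` attributes.
#' @export
validate_fiducials <- function(fixed, moving_before, moving_after) {
  sets <- list(fixed, moving_before, moving_after)
  n <- nrow(fixed)
  if (any(vapply(sets, nrow, 1L) != n)) stop_cfg("fiducial counts differ")
  if (!all(moving_before$label == fixed$label) ||
      !all(moving_after$label == fixed$label))
    stop_cfg("fiducial labels do not match")
  dist_ip <- function(a, b) sqrt((a$row - b$row)^2 + (a$col - b$col)^2)
  before <- dist_ip(moving_before, fixed)
  after <- dist_ip(moving_after, fixed)
  out <- data.frame(label = fixed$label, slice = fixed$slice,
                    dist_before = before, dist_after = after)
  structure(out,
            median_before = stats::median(before),
            median_after = stats::median(after),
            iqr_before = stats::IQR(before),
            iqr_after = stats::IQR(after),
            class = c("registration_report", "data.frame"))
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("Fiducial registration error (%d points, in-plane pixels)\n", nrow(x)))
  cat(sprintf("  before: median %.2f (IQR %.2f)\n",
              attr(x, "median_before"), attr(x, "iqr_before")))
  cat(sprintf("  after:  median %.2f (IQR %.2f)\n",
              attr(x, "median_after"), attr(x, "iqr_after")))
  invisible(x)
}

#' Restrict a volume to a slice range
#'
#' Returns the subvolume covering the inclusive 1-based slice range,
#' typically slices 6 to 13 of a 15-slice acquisition (distal neck through
#' lung apex), where registration artifacts are limited.
#'
#' @param volume 3D array, 4D array (last dim preserved), or [fsf_volume()].
#' @param first,last inclusive 1-based slice bounds.
#' @return object of the same kind restricted to the slice range; attribute
#'   `slice_offset` records `first - 1`.
#' @export
constrain_slices <- function(volume, first = 6L, last = 13L) {
  nz <- if (inherits(volume, "fsf_volume")) dim(volume$fsf)[3] else dim(volume)[3]
  if (first < 1L || last > nz || first > last)
    stop_cfg("slice range [%d, %d] invalid for %d slices", first, last, nz)
  keep <- seq.int(first, last)
  if (inherits(volume, "fsf_volume")) {
    out <- fsf_volume(volume$fsf[, , keep, drop = FALSE],
                      volume$valid[, , keep, drop = FALSE],
                      voxel_mm = volume$voxel_mm)
  } else if (length(dim(volume)) == 4L) {
    out <- volume[, , keep, , drop = FALSE]
  } else {
    out <- volume[, , keep, drop = FALSE]
  }
  attr(out, "slice_offset") <- first - 1L
  out
}

# In-place variant used by the pipeline: voxels outside the slice range are
# removed from a logical mask without changing the grid shape.
mask_to_slices <- function(mask, first, last) {
  d <- dim(mask)
  keep <- array(FALSE, d)
  keep[, , seq.int(max(1L, first), min(d[3], last))] <- TRUE
  mask & keep
}
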