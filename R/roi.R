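# Tissue ROI construction on the thermoneutral FSF map. Manual slice-wise
# delineation is replaced by seed masks (phantom truth labels or
# user-supplied masks); the FSF display window used during delineation
# constrains only the ROI boundary, and voxels with erroneous separation
# results are removed. Erosion and bilateral merging mirror the processing
# applied to hand-drawn ROIs.

# In-plane 4-connected boundary of a mask (per slice).
mask_boundary <- function(mask) {
  d <- dim(mask)
  inner <- mask &
    shift_mask(mask, 1, 1) & shift_mask(mask, -1, 1) &
    shift_mask(mask, 1, 2) & shift_mask(mask, -1, 2)
  mask & !inner
}

# Shift a logical mask with FALSE padding.
shift_mask <- function(mask, s, along) {
  d <- dim(mask)
  out <- array(FALSE, d)
  n <- d[along]
  src <- seq_len(n) + s
  ok <- src >= 1L & src <= n
  if (!any(ok)) return(out)
  if (along == 1L) out[which(ok), , ] <- mask[src[ok], , , drop = FALSE]
  else if (along == 2L) out[, which(ok), ] <- mask[, src[ok], , drop = FALSE]
  else out[, , which(ok)] <- mask[, , src[ok], drop = FALSE]
  out
}

#' Erode a mask once
#'
#' One in-plane morphological erosion with a 4-connected (plus-shaped)
#' structuring element, applied slice-wise, to reduce partial-volume
#' contamination at ROI boundaries.
#'
#' @param mask logical 3D array.
#' @return eroded logical array.
#' @examples
#' m <- array(FALSE, c(3, 3, 1)); m[, , 1] <- TRUE
#' sum(erode_once(m))  # 1 (the centre voxel)
#' @export
erode_once <- function(mask) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop_cfg("mask must be a logical 3D array")
  mask &
    shift_mask(mask, 1, 1) & shift_mask(mask, -1, 1) &
    shift_mask(mask, 1, 2) & shift_mask(mask, -1, 2)
}

#' Merge bilateral ROIs
#'
#' Union of disjoint left and right masks into a single bilateral ROI.
#'
#' @param left_mask,right_mask logical arrays of identical shape, disjoint.
#' @return merged logical array.
#' @export
merge_bilateral <- function(left_mask, right_mask) {
  if (!identical(dim(left_mask), dim(right_mask))) stop_cfg("mask shape mismatch")
  if (any(left_mask & right_mask)) stop_cfg("left and right masks overlap")
  left_mask | right_mask
}

#' Apply an FSF threshold window to an ROI
#'
#' Retains the voxels whose thermoneutral FSF lies in `[lo, hi]` (%). The
#' resulting membership is frozen: later acquisitions are summarized over
#' exactly these voxels.
#'
#' @param fsf_tn thermoneutral [fsf_volume()].
#' @param mask logical ROI mask.
#' @param lo,hi threshold bounds, `0 <= lo < hi <= 100`.
#' @return thresholded logical mask.
#' @export
apply_fsf_threshold <- function(fsf_tn, mask, lo, hi) {
  check_scalar(lo, "lo", 0, 100); check_scalar(hi, "hi", 0, 100)
  if (lo >= hi) stop_cfg("need lo < hi")
  if (!identical(dim(mask), dim(fsf_tn$fsf))) stop_cfg("mask shape mismatch")
  keep <- mask & fsf_tn$valid & !is.na(fsf_tn$fsf) &
    fsf_tn$fsf >= lo & fsf_tn$fsf <= hi
  keep[is.na(keep)] <- FALSE
  keep
}

#' Build tissue ROIs on the thermoneutral FSF map
#'
#' Starting from seed masks (phantom truth labels or user-drawn masks),
#' removes voxels with invalid/erroneous separation results, and for the BAT
#' ROI applies the delineation-time FSF display window to boundary
#' candidates only: boundary voxels whose thermoneutral FSF falls outside
#' the window are trimmed, while interior membership is untouched (the
#' window guided drawing of the outline, it is not an FSF threshold).
#'
#' @param fsf_tn thermoneutral [fsf_volume()].
#' @param seed_masks named list of logical masks; recognized names are
#'   `bat_left`, `bat_right` (or a single `bat`), `sat`, `muscle`.
#' @param display_window FSF window (%) constraining BAT boundary
#'   candidates at delineation; `c(0, 100)` disables the restriction.
#' @return object of class `tissue_roi_set`: list of masks (`bat_left`,
#'   `bat_right` if supplied, plus `sat`, `muscle`), the window used, and a
#'   `merged` flag (set by [merge_roi_sides()]).
#' @export
build_roi <- function(fsf_tn, seed_masks, display_window = c(30, 80)) {
  if (!inherits(fsf_tn, "fsf_volume")) stop_cfg("fsf_tn must be an fsf_volume")
  if (!length(seed_masks)) stop_cfg("no seed masks supplied")
  if (!any(fsf_tn$valid)) stop_cfg("FSF map contains no valid voxels")
  lo <- display_window[1]; hi <- display_window[2]
  if (lo >= hi) stop_cfg("invalid display window")
  out <- list()
  for (nm in names(seed_masks)) {
    m <- seed_masks[[nm]]
    if (!any(m)) stop_cfg("seed mask '%s' is empty", nm)
    m <- m & fsf_tn$valid
    if (!any(m)) stop_cfg("seed mask '%s' has no valid voxels", nm)
    if (grepl("^bat", nm) && (lo > 0 || hi < 100)) {
      bd <- mask_boundary(m)
      drop <- bd & (fsf_tn$fsf < lo | fsf_tn$fsf > hi)
      drop[is.na(drop)] <- FALSE
      m <- m & !drop
    }
    out[[nm]] <- m
  }
  structure(list(masks = out, display_window = display_window,
                 merged = FALSE),
            class = "tissue_roi_set")
}

#' Merge the left/right BAT sides of an ROI set
#'
#' @param roi a `tissue_roi_set` with `bat_left` and `bat_right` masks.
#' @return the ROI set with a single bilateral `bat` mask and `merged = TRUE`.
#' @export
merge_roi_sides <- function(roi) {
  if (is.null(roi$masks$bat_left) || is.null(roi$masks$bat_right))
    return(roi)
  roi$masks$bat <- merge_bilateral(roi$masks$bat_left, roi$masks$bat_right)
  roi$masks$bat_left <- NULL
  roi$masks$bat_right <- NULL
  roi$merged <- TRUE
  roi
}

#' @export
print.tissue_roi_set <- function(x, ...) {
  cat(sprintf("Tissue ROI set (window %g-%g%%, %s):\n",
              x$display_window[1], x$display_window[2],
              if (x$merged) "bilateral merged" else "sides separate"))
  for (nm in names(x$masks))
    cat(sprintf("  %-9s %d voxels\n", nm, sum(x$masks[[nm]])))
  invisible(x)
}
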