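# Multi-peak fat-water separation. Per voxel, (W, F, psi, R2*) minimize the
# squared residual to the complex signal model via variable projection: for a
# candidate (psi, R2*) the complex amplitudes (w, f) have a closed form, so
# the search is over the two nonlinear parameters only. Field-map ambiguity
# (fat-water swaps) is resolved by a multiresolution region-growing pass that
# keeps the field map spatially coherent before per-voxel refinement.

# VARPRO residual and amplitudes for per-voxel psi (Hz) and r2s (1/s).
# S: K x V complex; te_s: length K; ck: complex fat modulation (length K).
fw_varpro <- function(S, te_s, ck, psi, r2s, amplitudes = FALSE) {
  K <- length(te_s)
  dd <- exp(-outer(te_s, r2s))                    # K x V, real decay
  ph <- exp(-1i * 2 * pi * outer(te_s, psi))      # conj demodulation
  d2 <- dd * dd
  G11 <- .colSums(d2, K, ncol(d2))
  G12 <- colSums(d2 * ck)
  G22 <- .colSums(d2 * Mod(ck)^2, K, ncol(d2))
  M <- dd * ph * S
  z1 <- colSums(M)
  z2 <- colSums(Conj(ck) * M)
  det <- G11 * G22 - Mod(G12)^2
  det[det < 1e-300] <- 1e-300
  w <- (G22 * z1 - G12 * z2) / det
  f <- (G11 * z2 - Conj(G12) * z1) / det
  energy <- Re(Conj(w) * z1 + Conj(f) * z2)
  resid <- pmax(.colSums(Mod(S)^2, K, ncol(S)), 0) - energy
  if (amplitudes) list(resid = pmax(resid, 0), w = w, f = f)
  else list(resid = pmax(resid, 0))
}

# Shared-candidate residuals: psi and r2s scalars, all voxels at once.
fw_resid_shared <- function(S, te_s, ck, psi, r2s, S2 = NULL) {
  K <- length(te_s)
  dd <- exp(-te_s * r2s)
  b1c <- dd * exp(-1i * 2 * pi * psi * te_s)
  d2 <- dd * dd
  G11 <- sum(d2)
  G12 <- sum(d2 * ck)
  G22 <- sum(d2 * Mod(ck)^2)
  M <- b1c * S
  z1 <- colSums(M)
  z2 <- colSums(Conj(ck) * M)
  det <- max(G11 * G22 - Mod(G12)^2, 1e-300)
  w <- (G22 * z1 - G12 * z2) / det
  f <- (G11 * z2 - Conj(G12) * z1) / det
  if (is.null(S2)) S2 <- .colSums(Mod(S)^2, K, ncol(S))
  pmax(S2 - Re(Conj(w) * z1 + Conj(f) * z2), 0)
}

# Residual profile over a psi grid, minimized over an R2* grid.
# Returns npsi x V matrix plus the argmin R2* index per (psi, voxel).
fw_profile <- function(S, te_s, ck, psi_grid, r2s_grid) {
  V <- ncol(S)
  S2 <- .colSums(Mod(S)^2, length(te_s), V)
  P <- matrix(Inf, length(psi_grid), V)
  for (j in seq_along(psi_grid)) {
    best <- rep(Inf, V)
    for (r in r2s_grid) {
      rr <- fw_resid_shared(S, te_s, ck, psi_grid[j], r, S2 = S2)
      best <- pmin(best, rr)
    }
    P[j, ] <- best
  }
  P
}

# Region-growing field-map selection on a residual profile. coords: V x 3
# integer voxel coordinates; mag: signal magnitude (seed & priority).
fw_region_grow <- function(P, psi_grid, coords, mag, window_hz = 60) {
  V <- ncol(P)
  if (V == 1L) return(psi_grid[which.min(P[, 1])])
  np <- nrow(P)
  is_min <- P <= rbind(P[1, , drop = FALSE], P[-np, , drop = FALSE]) &
    P <= rbind(P[-1, , drop = FALSE], P[np, , drop = FALSE])
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (v in seq_len(V)) assign(key[v], v, envir = index)
  est <- rep(NA_real_, V)
  seed <- which.max(mag)
  est[seed] <- psi_grid[which.min(P[, seed])]
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  queue <- seed
  head <- 1L
  visited <- rep(FALSE, V)
  visited[seed] <- TRUE
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (o in seq_len(6)) {
      nk <- paste(coords[v, 1] + offsets[o, 1], coords[v, 2] + offsets[o, 2],
                  coords[v, 3] + offsets[o, 3])
      nb <- index[[nk]]
      if (is.null(nb) || visited[nb]) next
      visited[nb] <- TRUE
      prior <- est[v]
      ok <- abs(psi_grid - prior) <= window_hz
      cand <- which(ok & is_min[, nb])
      if (!length(cand)) cand <- which(ok)
      if (!length(cand)) cand <- which.min(abs(psi_grid - prior))
      est[nb] <- psi_grid[cand[which.min(P[cand, nb])]]
      queue <- c(queue, nb)
    }
  }
  est[!visited] <- stats::median(est[visited])
  est
}

# One parabolic line-search round on a per-voxel parameter.
fw_parab_step <- function(S, te_s, ck, psi, r2s, h, param = c("psi", "r2s"),
                          lower = -Inf, upper = Inf) {
  param <- match.arg(param)
  ev <- function(p) {
    if (param == "psi") fw_varpro(S, te_s, ck, p, r2s)$resid
    else fw_varpro(S, te_s, ck, psi, p)$resid
  }
  x0 <- if (param == "psi") psi else r2s
  f_m <- ev(pmax(x0 - h, lower)); f_0 <- ev(x0); f_p <- ev(pmin(x0 + h, upper))
  denom <- f_m - 2 * f_0 + f_p
  step <- ifelse(abs(denom) > 1e-300, 0.5 * h * (f_m - f_p) / denom, 0)
  step <- pmin(pmax(step, -h), h)
  # fall back to the best sampled point where the parabola is degenerate
  best <- max.col(-cbind(f_m, f_0, f_p), ties.method = "first")
  x_new <- x0 + step
  x_new <- ifelse(abs(denom) > 1e-300, x_new,
                  x0 + h * c(-1, 0, 1)[best])
  pmin(pmax(x_new, lower), upper)
}

#' Separation options
#'
#' Tuning parameters for [separate_fat_water()]. The field-map search is a
#' bounded grid (default +/- 1.5x the Nyquist frequency of the mean echo
#' spacing, capped at `psi_range_hz`) evaluated on an in-plane downsampled
#' volume, made spatially coherent by region growing, then refined per voxel
#' together with R2* by parabolic line searches.
#'
#' @param psi_range_hz half-width of the field-map search range (Hz); `NULL`
#'   uses 1.5x the Nyquist frequency of the mean echo spacing.
#' @param psi_step_hz coarse grid step (Hz).
#' @param r2s_grid coarse R2* candidates (1/s).
#' @param r2s_max upper bound for R2* refinement (1/s).
#' @param downsample in-plane downsampling factor of the field-map pass.
#' @param window_hz neighbor consistency window of the region growing (Hz).
#' @param offsets_hz per-voxel offsets around the propagated field-map prior.
#' @param refine_rounds parabolic refinement rounds per parameter.
#' @param fit_threshold_frac voxels with first-echo magnitude below this
#'   fraction of the 99th-percentile magnitude are flagged invalid, not
#'   fitted.
#' @param fieldmap_smooth_vox Gaussian sigma (coarse voxels) smoothing the
#'   grown field map before refinement.
#' @param fitting `"complex"` (default) fits the complex signal;
#'   `"magnitude"` fits echo magnitudes only (noise-bias experiments).
#' @return list of class `separation_options`.
#' @export
separation_options <- function(psi_range_hz = NULL, psi_step_hz = 4,
                               r2s_grid = c(0, 20, 45, 80, 120),
                               r2s_max = 200, downsample = 4L,
                               window_hz = 60, offsets_hz = seq(-24, 24, 8),
                               refine_rounds = 7L, fit_threshold_frac = 0.02,
                               fieldmap_smooth_vox = 1, fitting = c("complex", "magnitude")) {
  structure(list(psi_range_hz = psi_range_hz, psi_step_hz = psi_step_hz,
                 r2s_grid = r2s_grid, r2s_max = r2s_max,
                 downsample = as.integer(downsample), window_hz = window_hz,
                 offsets_hz = offsets_hz, refine_rounds = refine_rounds,
                 fit_threshold_frac = fit_threshold_frac,
                 fieldmap_smooth_vox = fieldmap_smooth_vox,
                 fitting = match.arg(fitting)),
            class = "separation_options")
}

# In-plane block-average downsampling of a complex volume (factor f).
downsample_inplane <- function(vol, f) {
  d <- dim(vol)
  n1 <- d[1] %/% f; n2 <- d[2] %/% f
  v <- vol[seq_len(n1 * f), seq_len(n2 * f), , drop = FALSE]
  a <- array(v, c(f, n1, f, n2, d[3]))
  out <- apply(a, c(2, 4, 5), mean)
  array(out, c(n1, n2, d[3]))
}

#' Separate water and fat from a multi-echo series
#'
#' Estimates per voxel the water and fat magnitudes, field-map offset psi
#' (Hz) and common R2* (1/s) that minimize the squared residual to the
#' multi-peak complex signal model. The field map is first estimated on an
#' in-plane downsampled volume over the full bounded psi range, made
#' spatially coherent by region growing from a high-signal seed (avoiding
#' fat-water swaps), then propagated to full resolution and refined per
#' voxel jointly with R2*. Voxels with negligible first-echo magnitude are
#' flagged invalid and not fitted.
#'
#' @param series an `echo_series` (at least 4 echoes).
#' @param spectrum a [fat_spectrum()].
#' @param options a [separation_options()].
#' @return object of class `separation_result` with arrays `W`, `F`, `psi`,
#'   `r2star`, `residual`, `valid`, `mag1`.
#' @export
separate_fat_water <- function(series, spectrum = fat_spectrum(),
                               options = separation_options()) {
  if (!inherits(series, "echo_series")) stop_cfg("series must be an echo_series")
  d <- dim(series$data)[1:3]
  K <- dim(series$data)[4]
  if (K < 4L) stop_cfg("need at least 4 echoes")
  te_s <- series$schedule$te_ms / 1000
  ck <- fat_modulation(spectrum, te_s)
  mag1 <- array(Mod(series$data[, , , 1, drop = FALSE]), d)
  q99 <- stats::quantile(mag1, 0.99, names = FALSE)
  fit_mask <- mag1 > options$fit_threshold_frac * q99
  V <- sum(fit_mask)
  res <- list(W = array(0, d), F = array(0, d), total = array(0, d),
              psi = array(0, d), r2star = array(0, d), residual = array(0, d),
              valid = fit_mask, mag1 = mag1, voxel_mm = series$voxel_mm,
              options = options)
  class(res) <- "separation_result"
  if (V == 0L) return(res)

  if (is.null(options$psi_range_hz)) {
    spacing <- mean(diff(sort(te_s)))
    psi_range <- 1.5 / (2 * spacing)
  } else psi_range <- options$psi_range_hz
  psi_grid <- seq(-psi_range, psi_range, by = options$psi_step_hz)

  Smat <- t(matrix(series$data, prod(d), K))   # K x all voxels
  if (options$fitting == "magnitude") {
    fit <- fw_fit_magnitude(Mod(Smat[, fit_mask, drop = FALSE]), te_s, ck, options)
    prior_fine <- rep(0, V)
    psi_hat <- rep(0, V); r2s_hat <- fit$r2s
    w_amp <- fit$W; f_amp <- fit$F; resid <- fit$resid
    total <- w_amp + f_amp
  } else {
    # --- coarse field map on downsampled volume ---
    f <- max(1L, min(options$downsample, min(d[1:2]) %/% 8L))
    if (f > 1L && V > 64L) {
      dn <- c(d[1] %/% f, d[2] %/% f, d[3])
      Sc <- array(0i, c(dn, K))
      for (k in seq_len(K)) Sc[, , , k] <- downsample_inplane(series$data[, , , k], f)
      magc <- array(Mod(Sc[, , , 1, drop = FALSE]), dn)
      maskc <- magc > options$fit_threshold_frac * stats::quantile(magc, 0.99, names = FALSE)
      Vc <- sum(maskc)
      Scm <- t(matrix(Sc, prod(dn), K))[, as.vector(maskc), drop = FALSE]
      P <- fw_profile(Scm, te_s, ck, psi_grid, options$r2s_grid)
      gc3 <- coord_grids(dn)
      coords <- cbind(gc3$x, gc3$y, gc3$z)[as.vector(maskc), , drop = FALSE]
      estc <- fw_region_grow(P, psi_grid, coords, magc[maskc], options$window_hz)
      psi_c <- array(NA_real_, dn)
      psi_c[maskc] <- estc
      # fill unfitted coarse voxels from the fitted median, then smooth
      psi_c[!maskc] <- stats::median(estc)
      psi_c <- gauss_smooth3(psi_c, rep(options$fieldmap_smooth_vox, 2))
      gf <- coord_grids(d)
      prior_all <- interp3(psi_c, gf$x / f + (0.5 - 0.5 / f),
                           gf$y / f + (0.5 - 0.5 / f), gf$z, clamp = TRUE)
      prior_fine <- prior_all[as.vector(fit_mask)]
    } else {
      Sm <- Smat[, as.vector(fit_mask), drop = FALSE]
      P <- fw_profile(Sm, te_s, ck, psi_grid, options$r2s_grid)
      prior_fine <- psi_grid[max.col(t(-P), ties.method = "first")]
    }

    S <- Smat[, as.vector(fit_mask), drop = FALSE]
    # --- per-voxel search around the propagated prior ---
    best_r <- rep(Inf, V); psi_hat <- prior_fine; r2s_hat <- rep(0, V)
    S2 <- .colSums(Mod(S)^2, K, V)
    phP <- exp(-1i * 2 * pi * outer(te_s, prior_fine)) * S
    for (off in options$offsets_hz) {
      e_off <- exp(-1i * 2 * pi * off * te_s)
      for (r in options$r2s_grid) {
        dd <- exp(-te_s * r)
        b <- dd * e_off
        M <- b * phP
        z1 <- colSums(M)
        z2 <- colSums(Conj(ck) * M)
        d2 <- dd * dd
        G11 <- sum(d2); G12 <- sum(d2 * ck); G22 <- sum(d2 * Mod(ck)^2)
        det <- max(G11 * G22 - Mod(G12)^2, 1e-300)
        w <- (G22 * z1 - G12 * z2) / det
        fc <- (G11 * z2 - Conj(G12) * z1) / det
        rr <- pmax(S2 - Re(Conj(w) * z1 + Conj(fc) * z2), 0)
        upd <- rr < best_r
        best_r[upd] <- rr[upd]
        psi_hat[upd] <- prior_fine[upd] + off
        r2s_hat[upd] <- r
      }
    }
    # --- joint parabolic refinement ---
    h_psi <- options$psi_step_hz * 1.5
    h_r2s <- max(diff(options$r2s_grid)) / 2
    for (round in seq_len(options$refine_rounds)) {
      psi_hat <- fw_parab_step(S, te_s, ck, psi_hat, r2s_hat, h_psi, "psi",
                               lower = -psi_range - 50, upper = psi_range + 50)
      r2s_hat <- fw_parab_step(S, te_s, ck, psi_hat, r2s_hat, h_r2s, "r2s",
                               lower = 0, upper = options$r2s_max)
      h_psi <- h_psi / 4
      h_r2s <- h_r2s / 4
    }
    fin <- fw_varpro(S, te_s, ck, psi_hat, r2s_hat, amplitudes = TRUE)
    # align the common initial phase and take species magnitudes
    w_amp <- Mod(fin$w); f_amp <- Mod(fin$f)
    total <- Mod(fin$w + fin$f)
    resid <- fin$resid
  }
  res$W[fit_mask] <- w_amp
  res$F[fit_mask] <- f_amp
  res$total[fit_mask] <- total
  res$psi[fit_mask] <- psi_hat
  res$r2star[fit_mask] <- r2s_hat
  res$residual[fit_mask] <- resid
  res
}

# Magnitude-only fit: grid search over FSF and R2*, amplitude by linear LS
# on echo magnitudes. Exposed through separation_options(fitting =
# "magnitude") for noise-bias experiments.
fw_fit_magnitude <- function(Smag, te_s, ck, options) {
  V <- ncol(Smag)
  S2 <- colSums(Smag^2)
  fsf_grid <- seq(0, 100, by = 0.5)
  best <- list(resid = rep(Inf, V), fsf = rep(0, V), r2s = rep(0, V),
               A = rep(0, V))
  for (r in options$r2s_grid) {
    dd <- exp(-te_s * r)
    for (fr in fsf_grid) {
      m <- Mod((1 - fr / 100) + (fr / 100) * ck) * dd
      mm <- sum(m^2)
      A <- colSums(m * Smag) / mm
      rr <- pmax(S2 - A^2 * mm, 0)
      upd <- rr < best$resid
      best$resid[upd] <- rr[upd]; best$fsf[upd] <- fr
      best$r2s[upd] <- r; best$A[upd] <- A[upd]
    }
  }
  list(W = best$A * (1 - best$fsf / 100), F = best$A * best$fsf / 100,
       r2s = best$r2s, resid = best$resid)
}

#' @export
print.separation_result <- function(x, ...) {
  d <- dim(x$W)
  v <- x$valid
  cat(sprintf("Fat-water separation %d x %d x %d: %d fitted voxels\n",
              d[1], d[2], d[3], sum(v)))
  if (any(v))
    cat(sprintf("  field map %.1f .. %.1f Hz, median R2* %.1f 1/s\n",
                min(x$psi[v]), max(x$psi[v]), stats::median(x$r2star[v])))
  invisible(x)
}

#' Compute an FSF map from a separation result
#'
#' Calculates the per-voxel fat-signal fraction (%) from the water and fat
#' magnitudes using the dominant-signal convention: where water dominates,
#' `FSF = 100 F / (F + W)`; where fat dominates, `FSF = 100 (1 - W / (F + W))`.
#' The two branches are algebraically identical on exact inputs; the
#' branching matters only for estimators that bias the magnitude of the
#' weaker species. Background voxels (first-echo magnitude below
#' `background_threshold_frac` of the 99th-percentile magnitude), unfitted
#' voxels, voxels with `F + W = 0`, and erroneous results outside [0, 100]
#' are flagged invalid.
#'
#' @param result a `separation_result`.
#' @param background_threshold_frac background removal threshold (fraction
#'   of the robust maximum first-echo magnitude).
#' @return an [fsf_volume()].
#' @export
compute_fsf_map <- function(result, background_threshold_frac = 0.05) {
  if (!inherits(result, "separation_result")) stop_cfg("need a separation_result")
  check_scalar(background_threshold_frac, "background_threshold_frac", 0, 1)
  W <- result$W; F_ <- result$F
  tot <- F_ + W
  q99 <- stats::quantile(result$mag1, 0.99, names = FALSE)
  valid <- result$valid & result$mag1 >= background_threshold_frac * q99 &
    is.finite(tot) & tot > 0
  fsf <- array(NA_real_, dim(W))
  wd <- valid & W >= F_
  fd <- valid & W < F_
  fsf[wd] <- 100 * F_[wd] / tot[wd]
  fsf[fd] <- 100 * (1 - W[fd] / tot[fd])
  bad <- valid & (fsf < 0 | fsf > 100)
  valid[bad] <- FALSE
  fsf[!valid] <- NA_real_
  fsf_volume(fsf, valid, voxel_mm = result$voxel_mm)
}
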