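# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop_cfg("`%s` must be a finite scalar in [%g, %g]", name, lo, hi)
  x
}

#' Trilinear interpolation at arbitrary voxel coordinates
#'
#' Samples a 3D array at fractional voxel coordinates (1-based, array order
#' row/col/slice). Out-of-grid samples return `fill` unless `clamp = TRUE`,
#' in which case coordinates are clamped to the grid edge (replicate border).
#'
#' @param vol 3D numeric array.
#' @param x,y,z coordinate vectors along dims 1, 2, 3 (equal length).
#' @param fill value for out-of-grid samples when `clamp = FALSE`.
#' @param clamp clamp coordinates to the grid instead of filling.
#' @return numeric vector of sampled values.
#' @keywords internal
#' @noRd
interp3 <- function(vol, x, y, z, fill = NA_real_, clamp = FALSE) {
  d <- dim(vol)
  if (clamp) {
    x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2]); z <- pmin(pmax(z, 1), d[3])
    inside <- rep(TRUE, length(x))
  } else {
    inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3] &
      is.finite(x) & is.finite(y) & is.finite(z)
    x <- pmin(pmax(ifelse(inside, x, 1), 1), d[1])
    y <- pmin(pmax(ifelse(inside, y, 1), 1), d[2])
    z <- pmin(pmax(ifelse(inside, z, 1), 1), d[3])
  }
  i0 <- pmin(floor(x), d[1] - 1L); j0 <- pmin(floor(y), d[2] - 1L)
  k0 <- if (d[3] > 1L) pmin(floor(z), d[3] - 1L) else rep(1, length(z))
  fx <- x - i0; fy <- y - j0; fz <- if (d[3] > 1L) z - k0 else rep(0, length(z))
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- i0 + (j0 - 1) * n1 + (k0 - 1) * n12
  kz <- if (d[3] > 1L) n12 else 0L
  v <- (1 - fx) * (1 - fy) * (1 - fz) * vol[base] +
    fx * (1 - fy) * (1 - fz) * vol[base + 1] +
    (1 - fx) * fy * (1 - fz) * vol[base + n1] +
    fx * fy * (1 - fz) * vol[base + n1 + 1] +
    (1 - fx) * (1 - fy) * fz * vol[base + kz] +
    fx * (1 - fy) * fz * vol[base + kz + 1] +
    (1 - fx) * fy * fz * vol[base + kz + n1] +
    fx * fy * fz * vol[base + kz + n1 + 1]
  v[!inside] <- fill
  v
}

# Nearest-neighbour sampling; FALSE/fill outside the grid.
nn3 <- function(vol, x, y, z, fill = NA) {
  d <- dim(vol)
  i <- round(x); j <- round(y); k <- round(z)
  inside <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3] &
    is.finite(i) & is.finite(j) & is.finite(k)
  i <- pmin(pmax(ifelse(inside, i, 1), 1), d[1])
  j <- pmin(pmax(ifelse(inside, j, 1), 1), d[2])
  k <- pmin(pmax(ifelse(inside, k, 1), 1), d[3])
  v <- vol[cbind(i, j, k)]
  v[!inside] <- fill
  v
}

# Shift a 3D array by an integer offset along one dimension, replicating edges.
shift_edge <- function(arr, s, along) {
  d <- dim(arr)
  idx <- pmin(pmax(seq_len(d[along]) + s, 1L), d[along])
  switch(along,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

# Separable Gaussian smoothing with edge replication; sigma per dimension
# (voxels). sigma = 0 along a dimension skips it.
gauss_smooth3 <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3L)
  out <- arr
  for (dm in 1:3) {
    s <- sigma[dm]
    if (s <= 0 || dim(arr)[dm] == 1L) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim(arr))
    for (t in seq(-r, r)) acc <- acc + w[t + r + 1L] * shift_edge(out, t, dm)
    out <- acc
  }
  out
}

# Central-difference gradient of a 3D array (voxel units), edge replicated.
gradient3 <- function(arr) {
  g <- vector("list", 3L)
  for (dm in 1:3) {
    if (dim(arr)[dm] == 1L) {
      g[[dm]] <- array(0, dim(arr))
    } else {
      g[[dm]] <- (shift_edge(arr, 1L, dm) - shift_edge(arr, -1L, dm)) / 2
    }
  }
  g
}

# Coordinate grids (as vectors aligned with array storage order).
coord_grids <- function(d) {
  list(x = rep(seq_len(d[1]), times = d[2] * d[3]),
       y = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
       z = rep(seq_len(d[3]), each = d[1] * d[2]))
}

# Derive a bounded RNG seed for stage `k` from a top-level seed.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 977L + 7919L * as.integer(k) %% 1000003L
}
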