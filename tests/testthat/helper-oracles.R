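# Independent oracles, written as literal transcriptions of the underlying
# definitions, against which the vectorized implementations are checked.

# Closed-form multi-echo signal for a single voxel, one echo at a time.
oracle_signal <- function(W, F, psi, r2s, te_s, rel_amp, freq_hz) {
  vapply(te_s, function(te) {
    c_te <- sum(rel_amp * exp(1i * 2 * pi * freq_hz * te))
    (W + F * c_te) * exp(1i * 2 * pi * psi * te) * exp(-r2s * te)
  }, complex(1))
}

# Brute-force in-plane 4-connected erosion via explicit neighbour checks.
oracle_erode <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k]) next
    ok <- i > 1 && i < d[1] && j > 1 && j < d[2] &&
      mask[i - 1, j, k] && mask[i + 1, j, k] &&
      mask[i, j - 1, k] && mask[i, j + 1, k]
    out[i, j, k] <- ok
  }
  out
}

# Exact two-sided signed-rank p by explicit enumeration of sign vectors.
oracle_signed_rank_p <- function(w_obs, n) {
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wplus <- as.vector(signs %*% seq_len(n))
  total <- n * (n + 1) / 2
  w_min <- pmin(wplus, total - wplus)
  mean(w_min <= min(w_obs, total - w_obs))
}

# Small default-size phantom series for separation tests.
make_test_series <- function(fsf_values, psi = 25, r2s = 40, noise_sd = 0,
                             seed = 1) {
  d <- c(length(fsf_values), 1L, 1L)
  synthesize_echoes(array(fsf_values, d), array(100, d), array(psi, d),
                    array(r2s, d), build_echo_schedule(), fat_spectrum(),
                    noise_sd = noise_sd, seed = seed)
}

# Shared small pipeline configuration (full default grid, short session).
small_run_config <- function(...) {
  bat_pipeline_config(n_acquisitions = 3L, ...)
}
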