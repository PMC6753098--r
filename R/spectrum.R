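#' Multi-peak spectral fat model
#'
#' Returns the relative amplitudes and frequency offsets of a multi-peak
#' triglyceride \eqn{^1}H spectrum used both to synthesize multi-echo signals
#' and to separate them into water and fat components. The default is a
#' standard published seven-peak adipose/liver model (methylene-dominant)
#' with amplitudes normalized to sum to one; frequency offsets are expressed
#' relative to the water resonance (4.70 ppm) and converted to Hz at the
#' requested field strength (42.5775 MHz/T).
#'
#' @param field_T static field strength in tesla.
#' @param ppm fat peak positions in ppm (chemical shift scale).
#' @param rel_amp relative peak amplitudes; normalized to sum to 1.
#' @param water_ppm water reference position in ppm.
#' @return object of class `fat_spectrum`: list with `rel_amp`,
#'   `freq_offset_hz` (fat minus water; negative for aliphatic peaks),
#'   `ppm_offset`, `field_T`.
#' @examples
#' sp <- fat_spectrum()
#' sum(sp$rel_amp)  # 1
#' @export
fat_spectrum <- function(field_T = 3,
                         ppm = c(0.90, 1.30, 1.60, 2.02, 2.24, 2.75, 5.29),
                         rel_amp = c(0.088, 0.642, 0.058, 0.062, 0.058, 0.006, 0.086),
                         water_ppm = 4.70) {
  if (length(ppm) != length(rel_amp)) stop_cfg("ppm and rel_amp lengths differ")
  if (any(rel_amp < 0)) stop_cfg("rel_amp must be nonnegative")
  s <- sum(rel_amp)
  if (s <= 0) stop_cfg("rel_amp must have positive sum")
  rel_amp <- rel_amp / s
  stopifnot(abs(sum(rel_amp) - 1) <= 1e-12)
  gamma_mhz_t <- 42.5774806
  hz_per_ppm <- gamma_mhz_t * field_T
  structure(list(rel_amp = rel_amp,
                 ppm_offset = ppm - water_ppm,
                 freq_offset_hz = (ppm - water_ppm) * hz_per_ppm,
                 hz_per_ppm = hz_per_ppm,
                 field_T = field_T),
            class = "fat_spectrum")
}

#' @export
print.fat_spectrum <- function(x, ...) {
  cat(sprintf("%d-peak fat spectrum at %.1f T\n", length(x$rel_amp), x$field_T))
  print(data.frame(ppm_offset = round(x$ppm_offset, 2),
                   freq_hz = round(x$freq_offset_hz, 1),
                   rel_amp = round(x$rel_amp, 4)))
  invisible(x)
}

# Complex fat modulation c_k = sum_p alpha_p exp(i 2 pi df_p TE_k), TE in s.
fat_modulation <- function(spectrum, te_s) {
  as.vector(exp(1i * 2 * pi * outer(te_s, spectrum$freq_offset_hz)) %*% spectrum$rel_amp)
}
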