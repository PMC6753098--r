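# Report figures (base graphics): ROI threshold comparison, decade endpoint
# comparison, and decade trajectories against normalized cooling dose and
# thermal sensation.

decade_cols <- function() grDevices::hcl.colors(10, "Zissou 1")

#' Plot thermoneutral vs cold-exposure means per ROI / threshold window
#' @param run a `bat_run`.
#' @export
plot_threshold_comparison <- function(run) {
  tab <- run$thresholds
  lab <- paste(toupper(tab$tissue), tab$window)
  x <- seq_len(nrow(tab))
  graphics::plot(NA, xlim = c(0.5, nrow(tab) + 0.5),
                 ylim = range(c(tab$mean_tn, tab$mean_ce)) + c(-5, 5),
                 xaxt = "n", xlab = "", ylab = "Mean FSF (%)",
                 main = "Cold-induced change by ROI and FSF threshold")
  graphics::axis(1, at = x, labels = lab, las = 2, cex.axis = 0.7)
  graphics::points(x - 0.15, tab$mean_tn, col = "firebrick", pch = 19)
  graphics::points(x + 0.15, tab$mean_ce, col = "steelblue", pch = 19)
  graphics::segments(x - 0.15, tab$mean_tn, x + 0.15, tab$mean_ce, col = "grey50")
  graphics::legend("bottomright", c("thermoneutral", "cold exposure"),
                   col = c("firebrick", "steelblue"), pch = 19, bty = "n")
  invisible(run)
}

#' Plot decade endpoint changes per tissue
#' @param run a `bat_run`.
#' @export
plot_decade_endpoints <- function(run) {
  tab <- run$endpoint
  tissues <- unique(tab$tissue)
  old <- graphics::par(mfrow = c(1, length(tissues)))
  on.exit(graphics::par(old))
  for (tis in tissues) {
    tt <- tab[tab$tissue == tis, ]
    graphics::barplot(tt$change, names.arg = tt$decade,
                      col = decade_cols()[tt$decade / 10 + 1],
                      xlab = "Initial FSF decade (%)",
                      ylab = "FSF change (pp)", main = toupper(tis))
    graphics::abline(h = 0)
  }
  invisible(run)
}

decade_traj_plot <- function(run, xvar, xlab, main) {
  s <- run$decades$bat
  cols <- decade_cols()
  graphics::plot(NA, xlim = range(s[[xvar]]), ylim = range(s$mean_fsf),
                 xlab = xlab, ylab = "Mean FSF (%)", main = main)
  for (dec in sort(unique(s$decade))) {
    sd_ <- s[s$decade == dec, ]
    o <- order(sd_[[xvar]])
    graphics::points(sd_[[xvar]][o], sd_$mean_fsf[o],
                     col = cols[dec / 10 + 1], pch = 19, cex = 0.6)
    fit <- stats::lm(mean_fsf ~ x, data = data.frame(mean_fsf = sd_$mean_fsf,
                                                     x = sd_[[xvar]]))
    graphics::abline(fit, col = cols[dec / 10 + 1])
  }
  graphics::legend("right", legend = paste0(seq(0, 90, 10), "%"),
                   col = cols, lty = 1, cex = 0.6, bty = "n",
                   title = "decade")
  invisible(run)
}

#' Plot BAT decade mean FSF against normalized cooling dose
#' @param run a `bat_run`.
#' @export
plot_decade_dose_correlation <- function(run) {
  decade_traj_plot(run, "norm_dose",
                   expression("Normalized cooling dose (" * degree * "C min m"^-2 * ")"),
                   "BAT decade FSF vs cooling dose")
}

#' Plot BAT decade mean FSF against thermal sensation
#' @param run a `bat_run`.
#' @export
plot_decade_sensation_correlation <- function(run) {
  decade_traj_plot(run, "sensation", "Thermal sensation (50 = neutral, 0 = very cold)",
                   "BAT decade FSF vs thermal sensation")
}

#' @export
plot.bat_run <- function(x, ...) {
  plot_decade_endpoints(x)
}
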