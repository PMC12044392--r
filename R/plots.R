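# Figure-style plots: volume/time with phase demarcation, phase-1 detail
# panels, full-span variable panels, PA-scan comparison. Base graphics.

.phase_lines <- function(ph) {
  if (is.null(ph)) return(invisible())
  graphics::abline(v = ph$t_trough / 24, lty = 3, col = "grey40")
  if (!is.na(ph$t_inhibition))
    graphics::abline(v = ph$t_inhibition / 24, lty = 3, col = "grey40")
}

#' Plot an ISC simulation
#'
#' `which = "volume"` draws the relative volume over the full run with
#' the three phases demarcated; `"phase1"` the first 1.2 days of the key
#' variables (volume, contents, concentrations, Gardos K efflux, Em,
#' pH); `"full"` the full-span panels (Em vs the Nernst potentials, the
#' hemoglobin osmotic contribution, Hb and X charge concentrations,
#' total/free Mg, contents, concentrations, Na-pump flux, rA and rH).
#'
#' @param x an `isc_sim`.
#' @param which one of `"volume"`, `"phase1"`, `"full"`.
#' @param ... passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.isc_sim <- function(x, which = c("volume", "phase1", "full"), ...) {
  which <- match.arg(which)
  ts <- x$timeseries
  d <- ts$t / 24
  switch(which,
    volume = {
      graphics::plot(d, ts$relvol, type = "l", col = "grey60",
                     xlab = "time in circulation (days)",
                     ylab = "relative cell volume", ...)
      tr <- x$transits
      cyc <- cumsum(tr$kind == "oxy")
      rv <- vapply(split(seq_len(nrow(tr)), cyc), function(i)
        sum(tr$mean_relvol[i] * tr$duration_s[i]) / sum(tr$duration_s[i]), 0)
      tc <- vapply(split(seq_len(nrow(tr)), cyc), function(i)
        (min(tr$t_start[i]) + max(tr$t_end[i])) / 48, 0)
      graphics::lines(tc, rv, lwd = 2)
      .phase_lines(x$phases)
    },
    phase1 = {
      sel <- ts$t <= 28.8   # first 1.2 days
      s <- ts[sel, ]
      dd <- s$t / 24
      op <- graphics::par(mfrow = c(3, 2), mar = c(4, 4, 1.5, 1))
      on.exit(graphics::par(op))
      graphics::plot(dd, s$relvol, type = "l",
                     xlab = "days", ylab = "relative volume")
      graphics::matplot(dd, cbind(s$QNa, s$QK, s$QA), type = "l",
                        lty = 1, col = c(2, 4, 1),
                        xlab = "days", ylab = "contents (mmol/Loc)")
      graphics::legend("topright", c("Na", "K", "A"), col = c(2, 4, 1),
                       lty = 1, bty = "n")
      graphics::matplot(dd, cbind(s$CNa, s$CK, s$CA), type = "l",
                        lty = 1, col = c(2, 4, 1),
                        xlab = "days", ylab = "concentrations (mmol/Lcw)")
      graphics::plot(dd, s$JK_gardos, type = "l",
                     xlab = "days", ylab = "Gardos K flux (mmol/Loch)")
      graphics::plot(dd, s$Em, type = "l",
                     xlab = "days", ylab = "Em (mV)")
      graphics::plot(dd, s$pHi, type = "l",
                     xlab = "days", ylab = "cell pH")
    },
    full = {
      op <- graphics::par(mfrow = c(4, 2), mar = c(4, 4, 1.5, 1))
      on.exit(graphics::par(op))
      graphics::matplot(d, cbind(ts$Em, ts$EA, ts$EK, ts$ENa), type = "l",
                        lty = 1, col = c(1, 3, 4, 2),
                        xlab = "days", ylab = "potential (mV)")
      graphics::legend("bottomleft", c("Em", "EA", "EK", "ENa"),
                       col = c(1, 3, 4, 2), lty = 1, bty = "n", cex = 0.8)
      graphics::plot(d, ts$Hb_osm, type = "l",
                     xlab = "days", ylab = "fHb*CHb (mOsmol/Lcw)")
      graphics::matplot(d, cbind(ts$Hb_charge, -coef_x(x) * ts$CX),
                        type = "l", lty = 1, col = c(1, 2), xlab = "days",
                        ylab = "charge (mEq/Lcw)")
      graphics::legend("topleft", c("[Hb]", "[X] (-)"), col = c(1, 2),
                       lty = 1, bty = "n", cex = 0.8)
      graphics::matplot(d, cbind(ts$MgT, ts$MgF), type = "l", lty = 1,
                        col = c(1, 4), xlab = "days",
                        ylab = "Mg (mmol/Lcw)")
      graphics::matplot(d, cbind(ts$QNa, ts$QK, ts$QA), type = "l",
                        lty = 1, col = c(2, 4, 1),
                        xlab = "days", ylab = "contents (mmol/Loc)")
      graphics::matplot(d, cbind(ts$CNa, ts$CK, ts$CA), type = "l",
                        lty = 1, col = c(2, 4, 1),
                        xlab = "days", ylab = "concentrations (mmol/Lcw)")
      graphics::plot(d, ts$JNa_pump, type = "l",
                     xlab = "days", ylab = "Na-pump flux (mmol/Loch)")
      graphics::matplot(d, cbind(ts$rA, ts$rH), type = "l", lty = 1,
                        col = c(5, 3), xlab = "days", ylab = "rA, rH")
    })
  invisible(x)
}

coef_x <- function(sim) -unclass(sim$params)[["nX"]]

#' Write the standard figure set of a run
#'
#' Produces the three figure files (volume/time, phase-1 detail,
#' full-span panels) for visual quality control of a run.
#'
#' @param sim an `isc_sim`.
#' @param dir output directory (created if needed).
#' @param format `"png"` or `"svg"`.
#' @param width,height device size in pixels (png) or inches (svg).
#' @return character vector of the files written.
#' @export
plot_figures <- function(sim, dir, format = c("png", "svg"),
                         width = NULL, height = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(volume = c(900, 500), phase1 = c(900, 900),
                full = c(900, 1200))
  files <- character(0)
  for (w in names(specs)) {
    f <- file.path(dir, paste0(sim$protocol$name, "_", w, ".", format))
    wd <- width %||% specs[[w]][1]
    ht <- height %||% specs[[w]][2]
    if (format == "png") grDevices::png(f, width = wd, height = ht)
    else grDevices::svg(f, width = wd / 100, height = ht / 100)
    ok <- try(plot(sim, which = w), silent = TRUE)
    grDevices::dev.off()
    if (inherits(ok, "try-error")) stop("plotting '", w, "' failed: ",
                                        attr(ok, "condition")$message)
    files <- c(files, f)
  }
  files
}

#' Plot a PA scan
#'
#' One relative-volume trace per scanned deoxy-PIEZO1 anion
#' permeability, exposing its rate-limiting effect on the initial
#' dehydration and final rehydration rates.
#'
#' @param scan result of [scan_pa()].
#' @param ... passed to `plot`.
#' @return `scan`, invisibly.
#' @export
plot_pa_scan <- function(scan, ...) {
  runs <- attr(scan, "runs")
  cols <- c("red", "grey30", "blue", "darkgreen", "orange")
  rng <- range(unlist(lapply(runs, function(r) range(r$timeseries$relvol))))
  graphics::plot(NA, xlim = c(0, max(runs[[1]]$timeseries$t) / 24),
                 ylim = rng, xlab = "time in circulation (days)",
                 ylab = "relative cell volume", ...)
  for (i in seq_along(runs))
    graphics::lines(runs[[i]]$timeseries$t / 24,
                    runs[[i]]$timeseries$relvol,
                    col = cols[(i - 1) %% length(cols) + 1])
  graphics::legend("bottomleft",
                   legend = sprintf("PA = %.3g /h", scan$PA),
                   col = cols[seq_len(nrow(scan))], lty = 1, bty = "n")
  invisible(scan)
}
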