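# AE activity analysis: from a filtered hit stream to Pmaxrate, the water
# potential at maximum acoustic activity.

#' Filter AE hits by amplitude
#'
#' Retains hits at or above an amplitude threshold. Low-amplitude hits are
#' dominated by background noise; 45 dB is the conventional analysis
#' threshold for cavitation-related AE with 150 kHz resonant sensors.
#'
#' @param series An [ae_series].
#' @param min_amplitude_db Threshold in dB; hits with
#'   `amplitude_db >= min_amplitude_db` are kept. Default 45.
#' @return A filtered [ae_series]; the number of removed hits is reported
#'   as a message.
#' @export
filter_hits <- function(series, min_amplitude_db = 45) {
  stopifnot(inherits(series, "ae_series"))
  if (min_amplitude_db < 0 || min_amplitude_db > 120)
    stop("min_amplitude_db outside the sensor range [0, 120]")
  keep <- series$hits$amplitude_db >= min_amplitude_db
  message(sprintf("filter_hits: kept %d of %d hits (>= %g dB)",
                  sum(keep), length(keep), min_amplitude_db))
  out <- series
  out$hits <- series$hits[keep, , drop = FALSE]
  rownames(out$hits) <- NULL
  out
}

#' Compute the AE activity series (hits per minute)
#'
#' Converts a hit stream into acoustic activity: the number of hits per
#' minute, averaged over a sliding window (default 15 min) evaluated at
#' 1-min increments along the recording. The window is centered on each
#' grid point and truncated at the recording boundaries, with the count
#' divided by the actual window width so that the units stay hits per
#' minute everywhere.
#'
#' @param series An [ae_series] (typically after [filter_hits()]).
#' @param window_min Averaging window length in minutes (default 15).
#' @param step_min Grid increment in minutes (default 1).
#' @return An object of class `rate_series`: a list with `grid_times_min`,
#'   `raw_rate` (hits/min), `smoothed_rate` (NA until [smooth_rates()]),
#'   `window_min` and the smoothing parameters.
#' @export
compute_rate_series <- function(series, window_min = 15, step_min = 1) {
  stopifnot(inherits(series, "ae_series"))
  if (window_min < 1) stop("window_min must be >= 1 minute")
  dur_min <- series$t_end_s / 60
  if (dur_min < window_min)
    stop(sprintf("recording (%.1f min) is shorter than the %g-min window; ",
                 dur_min, window_min), "use a shorter window")
  if (nrow(series$hits) == 0)
    warning("no hits in series; activity is identically zero")
  grid <- seq(0, floor(dur_min / step_min) * step_min, by = step_min)
  half <- window_min / 2
  lo <- pmax(grid - half, 0)
  hi <- pmin(grid + half, dur_min)
  t_min <- sort(series$hits$time_s) / 60
  # half-open window [lo, hi): each hit falls in exactly window_min of the
  # unit-spaced windows, so no hit is double-counted at window edges
  n_in <- findInterval(hi, t_min, left.open = TRUE) -
    findInterval(lo, t_min, left.open = TRUE)
  raw <- n_in / (hi - lo)
  structure(list(grid_times_min = grid, raw_rate = raw,
                 smoothed_rate = rep(NA_real_, length(grid)),
                 window_min = window_min, sg_order = NA_integer_,
                 sg_window = NA_integer_),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("AE activity series: %d grid points (%g-min window)",
              length(x$grid_times_min), x$window_min))
  if (!all(is.na(x$smoothed_rate)))
    cat(sprintf(", smoothed (SG order %d, window %d)", x$sg_order,
                x$sg_window))
  cat(sprintf("\npeak raw rate %.2f hits/min\n", max(x$raw_rate)))
  invisible(x)
}

#' Smooth an AE activity series (Savitzky-Golay)
#'
#' Applies a Savitzky-Golay polynomial smoothing filter to the raw
#' activity series, reducing minute-to-minute variation while preserving
#' the position and shape of the activity peak (a moving polynomial fit
#' does not displace extrema the way a plain moving average does). Small
#' negative values produced by the polynomial fit near sharp features are
#' floored at zero.
#'
#' @param rates A `rate_series` from [compute_rate_series()].
#' @param sg_order Polynomial order of the filter (default 5).
#' @param sg_window Filter window length in grid points; must be odd and
#'   greater than `sg_order`. Default 7, the conventional minimal window
#'   for a 5th-order filter.
#' @return The `rate_series` with `smoothed_rate` populated.
#' @export
smooth_rates <- function(rates, sg_order = 5, sg_window = 7) {
  stopifnot(inherits(rates, "rate_series"))
  if (sg_window %% 2 != 1 || sg_window <= sg_order)
    stop("sg_window must be odd and greater than sg_order")
  n <- length(rates$raw_rate)
  if (n < sg_window)
    stop("activity series (", n, " points) shorter than the smoothing ",
         "window (", sg_window, "); use the raw-rate peak instead")
  sm <- signal::sgolayfilt(rates$raw_rate, p = sg_order, n = sg_window)
  n_neg <- sum(sm < 0)
  if (n_neg)
    message(sprintf("smooth_rates: floored %d negative smoothed value(s) at 0",
                    n_neg))
  rates$smoothed_rate <- pmax(sm, 0)
  rates$sg_order <- as.integer(sg_order)
  rates$sg_window <- as.integer(sg_window)
  rates
}

#' Time of maximum smoothed AE activity
#'
#' The grid time of the global maximum of the smoothed activity curve.
#' Ties are broken toward the earliest time, because spurious activity is
#' characteristic of the late stages of dehydration.
#'
#' @param rates A `rate_series` with `smoothed_rate` populated.
#' @return Time of the maximum, in minutes since recording start.
#' @export
find_max_rate_time <- function(rates) {
  stopifnot(inherits(rates, "rate_series"))
  sm <- rates$smoothed_rate
  if (all(is.na(sm)))
    stop("smoothed_rate not populated; call smooth_rates() first")
  if (all(sm == 0)) stop("no acoustic activity: smoothed rate is all zero")
  rates$grid_times_min[which.max(sm)]  # which.max takes the first maximum
}

#' Interpolate water potential at a given time
#'
#' Linear interpolation of Psi between the nearest previous and following
#' pressure-chamber readings. As a quality criterion, the interpolated
#' value should be within 0.3 MPa of the nearest measured reading;
#' otherwise the Psi sampling is too sparse around the requested time and
#' the result carries a failed QC flag.
#'
#' @param psi A [psi_series].
#' @param t_min Time in minutes since recording start; must lie within the
#'   span of the Psi readings (no extrapolation).
#' @param qc_tol_mpa QC tolerance in MPa (default 0.3).
#' @return A list with `psi_mpa` (signed), `qc_within_tol` (logical),
#'   and `bracketing` (the two readings used, as a 2-row data.frame; one
#'   row if `t_min` coincides with a reading).
#' @export
interpolate_psi <- function(psi, t_min, qc_tol_mpa = 0.3) {
  stopifnot(inherits(psi, "psi_series"))
  if (nrow(psi) < 2)
    stop("at least 2 Psi readings are required for interpolation")
  t_s <- t_min * 60
  if (t_s < psi$time_s[1] || t_s > psi$time_s[nrow(psi)])
    stop(sprintf(paste0("time %.1f min is outside the Psi observation span ",
                        "[%.1f, %.1f] min; refusing to extrapolate"),
                 t_min, psi$time_s[1] / 60, psi$time_s[nrow(psi)] / 60))
  i_hi <- which(psi$time_s >= t_s)[1]
  i_lo <- max(which(psi$time_s <= t_s))
  if (i_lo == i_hi || psi$time_s[i_lo] == psi$time_s[i_hi]) {
    val <- psi$psi_mpa[i_lo]
    bracketing <- psi[i_lo, c("time_s", "psi_mpa"), drop = FALSE]
  } else {
    w <- (t_s - psi$time_s[i_lo]) / (psi$time_s[i_hi] - psi$time_s[i_lo])
    val <- (1 - w) * psi$psi_mpa[i_lo] + w * psi$psi_mpa[i_hi]
    bracketing <- psi[c(i_lo, i_hi), c("time_s", "psi_mpa"), drop = FALSE]
  }
  nearest <- bracketing$psi_mpa[which.min(abs(bracketing$time_s - t_s))]
  rownames(bracketing) <- NULL
  list(psi_mpa = val,
       qc_within_tol = abs(val - nearest) <= qc_tol_mpa,
       bracketing = as.data.frame(bracketing))
}

#' Estimate Pmaxrate: water potential at maximum AE activity
#'
#' The full rate-based analysis chain for one dehydrating sample:
#' amplitude filtering, sliding-window activity computation,
#' Savitzky-Golay smoothing, peak localization, and linear interpolation
#' of Psi at the peak time. All intermediate series are retained in the
#' result for inspection and plotting.
#'
#' The method assumes an approximately steady Psi decline; when the Psi
#' trajectory is strongly nonlinear in time, a rate peak can reflect a
#' change of drying pace rather than a burst of cavitation, and a warning
#' is issued.
#'
#' @param series An [ae_series] (raw; filtering is applied internally).
#' @param psi A [psi_series] sharing the recording's time origin.
#' @param min_amplitude_db Amplitude threshold in dB (default 45).
#' @param window_min Activity averaging window, minutes (default 15).
#' @param sg_order,sg_window Savitzky-Golay parameters (defaults 5 and 7).
#' @param qc_tol_mpa Interpolation QC tolerance, MPa (default 0.3).
#' @return An object of class `pmaxrate_result`: a list with
#'   `pmaxrate_mpa` (signed), `t_max_min`, `peak_rate` (hits/min),
#'   `qc_within_tol`, `bracketing_readings`, `rates` (the full
#'   `rate_series`), `n_hits_used` and `sample_id`.
#' @examples
#' sim <- simulate_dehydration(sim_config(seed = 42))
#' res <- estimate_pmaxrate(sim$ae, sim$psi)
#' res$pmaxrate_mpa
#' @export
estimate_pmaxrate <- function(series, psi, min_amplitude_db = 45,
                              window_min = 15, sg_order = 5, sg_window = 7,
                              qc_tol_mpa = 0.3) {
  stopifnot(inherits(series, "ae_series"), inherits(psi, "psi_series"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("estimate_pmaxrate [", name, "]: ", conditionMessage(e),
           call. = FALSE))
  }
  filtered <- stage("filter", {
    f <- suppressMessages(filter_hits(series, min_amplitude_db))
    if (nrow(f$hits) == 0)
      stop("no hits at or above ", min_amplitude_db, " dB")
    f
  })
  rates <- stage("rate", compute_rate_series(filtered, window_min))
  rates <- stage("smooth", smooth_rates(rates, sg_order, sg_window))
  t_max <- stage("peak", find_max_rate_time(rates))
  interp <- stage("interpolate", interpolate_psi(psi, t_max, qc_tol_mpa))
  # flag strongly nonlinear drying: rate-based peaks can then track drying
  # pace rather than cavitation density
  if (nrow(psi) >= 3) {
    fit_lin <- stats::lm(psi_mpa ~ time_s, data = psi)
    r2 <- summary(fit_lin)$r.squared
    if (!is.na(r2) && r2 < 0.8)
      warning("Psi decline is strongly nonlinear in time (linear R^2 = ",
              sprintf("%.2f", r2), "); interpret the rate peak with care")
  }
  structure(list(pmaxrate_mpa = interp$psi_mpa,
                 t_max_min = t_max,
                 peak_rate = rates$smoothed_rate[
                   match(t_max, rates$grid_times_min)],
                 qc_within_tol = interp$qc_within_tol,
                 bracketing_readings = interp$bracketing,
                 rates = rates,
                 n_hits_used = nrow(filtered$hits),
                 sample_id = series$sample_id),
            class = "pmaxrate_result")
}

#' @export
print.pmaxrate_result <- function(x, ...) {
  cat(sprintf("Pmaxrate estimate for '%s'\n", x$sample_id))
  cat(sprintf("  Pmaxrate: %.2f MPa (QC %s)\n", x$pmaxrate_mpa,
              if (x$qc_within_tol) "passed" else "FAILED"))
  cat(sprintf("  peak activity: %.2f hits/min at t = %g min (%d hits used)\n",
              x$peak_rate, x$t_max_min, x$n_hits_used))
  invisible(x)
}

#' Plot an activity analysis
#'
#' Two-panel base-graphics figure: raw and smoothed AE activity over time
#' with the detected peak marked, and the Psi readings with their linear
#' interpolation.
#'
#' @param x A `pmaxrate_result`.
#' @param psi The [psi_series] used in the analysis (optional; omits the
#'   lower panel if missing).
#' @param log_time Plot time on a log axis (late-stage activity is easier
#'   to see); default FALSE.
#' @param ... Passed to `plot`.
#' @return Invisibly, `x`.
#' @export
plot.pmaxrate_result <- function(x, psi = NULL, log_time = FALSE, ...) {
  rates <- x$rates
  tt <- rates$grid_times_min
  if (log_time) tt <- pmax(tt, 0.5)
  op <- graphics::par(mfrow = c(if (is.null(psi)) 1 else 2, 1),
                      mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tt, rates$raw_rate, pch = 16, cex = 0.4, col = "grey40",
                 log = if (log_time) "x" else "",
                 xlab = "time (min)", ylab = "AE activity (hits/min)", ...)
  graphics::lines(tt, rates$smoothed_rate, col = "red", lwd = 2)
  graphics::abline(v = if (log_time) max(x$t_max_min, 0.5) else x$t_max_min,
                   col = "red", lty = 3)
  if (!is.null(psi)) {
    pt <- psi$time_s / 60
    if (log_time) pt <- pmax(pt, 0.5)
    graphics::plot(pt, psi$psi_mpa, col = "blue",
                   log = if (log_time) "x" else "",
                   xlab = "time (min)", ylab = expression(Psi ~ "(MPa)"))
    graphics::lines(pt, psi$psi_mpa, col = "blue", lty = 2)
    graphics::abline(h = x$pmaxrate_mpa, col = "red", lty = 3)
  }
  invisible(x)
}
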