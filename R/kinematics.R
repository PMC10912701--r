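#' Generate a synthetic run-up trace
#'
#' Simulates the radial distance from the player's head to the ball during the
#' run-up, sampled at `sampling_hz`. The underlying speed profile is
#' trapezoidal: acceleration `accel_mps2` from standstill up to the trial's
#' cruise speed, then constant speed until foot-ball contact (radius 0).
#' `accel_mps2 = Inf` gives uniform motion from the first sample. Trial-to-
#' trial variability multiplies the cruise speed by `1 + speed_cv * z` with
#' standard-normal `z`; per-sample position noise is additive Gaussian with SD
#' `noise_sd_m`, clamped at 0. `contact_time_s` is the ground-truth contact
#' time of the noiseless profile (what a LIDAR at the ball would time).
#'
#' @param start_radius_m Starting radial distance in m (>= 2, the minimum
#'   run-up distance).
#' @param speed_mps Nominal cruise speed in m/s (> 0).
#' @param accel_mps2 Acceleration in m/s^2 (> 0 or `Inf`).
#' @param speed_cv Coefficient of variation of the trial's cruise speed.
#' @param noise_sd_m Per-sample additive position noise SD in m.
#' @param sampling_hz Sampling rate in Hz (default 60, headset-like).
#' @return An object of class `runup_trace`: list with `t_s`, `radius_m`,
#'   `contact_time_s`, `sampling_hz`.
#' @export
generate_runup <- function(start_radius_m = 2.4, speed_mps = 4,
                           accel_mps2 = 4, speed_cv = 0, noise_sd_m = 0,
                           sampling_hz = 60) {
  if (start_radius_m < 2)
    stop("'start_radius_m' must be at least 2 m")
  if (speed_mps <= 0) stop("'speed_mps' must be positive")
  stopifnot(accel_mps2 > 0, sampling_hz > 0, speed_cv >= 0, noise_sd_m >= 0)
  v <- speed_mps * max(0.2, 1 + speed_cv * stats::rnorm(1))
  dt <- 1 / sampling_hz
  if (is.finite(accel_mps2)) {
    t_acc <- v / accel_mps2
    d_acc <- v^2 / (2 * accel_mps2)
    if (d_acc >= start_radius_m) {            # contact before reaching cruise
      t_contact <- sqrt(2 * start_radius_m / accel_mps2)
    } else {
      t_contact <- t_acc + (start_radius_m - d_acc) / v
    }
    dist_at <- function(t) {
      ifelse(t < t_acc, accel_mps2 * t^2 / 2, d_acc + v * (t - t_acc))
    }
  } else {
    t_contact <- start_radius_m / v
    dist_at <- function(t) v * t
  }
  t <- seq(0, t_contact, by = dt)
  if (t[length(t)] < t_contact) t <- c(t, t_contact)
  radius <- start_radius_m - dist_at(t)
  if (noise_sd_m > 0)
    radius <- radius + stats::rnorm(length(t), 0, noise_sd_m)
  radius <- pmax(radius, 0)
  structure(list(t_s = t, radius_m = radius, contact_time_s = t_contact,
                 sampling_hz = sampling_hz),
            class = "runup_trace")
}

#' @export
print.runup_trace <- function(x, ...) {
  cat(sprintf("Run-up trace: %d samples at %g Hz, start %.2f m, contact %.3f s\n",
              length(x$t_s), x$sampling_hz, x$radius_m[1], x$contact_time_s))
  invisible(x)
}

# Medians of y within integer groups, via one sort; returns groups in
# increasing order. Much faster than tapply for the per-trial map refits.
grouped_median <- function(group, y) {
  ord <- order(group, y)
  g_sorted <- group[ord]
  y_sorted <- y[ord]
  last <- which(diff(g_sorted) != 0)
  ends <- c(last, length(g_sorted))
  starts <- c(1L, last + 1L)
  mid <- (starts + ends) / 2
  med <- (y_sorted[floor(mid)] + y_sorted[ceiling(mid)]) / 2
  list(group = g_sorted[starts], median = med)
}

#' Fit a monotone time/radius mapping from run-up traces
#'
#' Estimates the remaining time-to-foot-ball-contact as a function of radial
#' distance to the ball, from one or more observed run-ups. All pre-contact
#' samples are pooled as (radius, remaining time) pairs and binned by radius
#' (`bin_width_m`). Each bin is summarised by the median remaining time and
#' median radius (robust to kinematic noise), monotonicity (time-to-contact
#' non-decreasing in radius) is enforced by isotonic pool-adjacent-violators
#' regression, and empty interior bins are filled by linear interpolation
#' between neighbouring bins.
#'
#' @param traces A `runup_trace` or list of them.
#' @param bin_width_m Radius bin width in m (default 0.05).
#' @return Object of class `radius_time_map`: `bin_edges_m`, per-bin
#'   representative `radius_m`, predicted `ttc_ms`, `n_traces`.
#' @export
fit_radius_time_map <- function(traces, bin_width_m = 0.05) {
  if (inherits(traces, "runup_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1, bin_width_m > 0)
  r <- unlist(lapply(traces, function(tr) tr$radius_m))
  ttc <- unlist(lapply(traces, function(tr) {
    (tr$contact_time_s - tr$t_s) * 1000
  }))
  keep <- ttc > 0 & r > 0
  r <- r[keep]; ttc <- ttc[keep]
  if (!length(r)) stop("no pre-contact samples to fit the map from")
  edges <- seq(0, max(r) + bin_width_m, by = bin_width_m)
  bin <- findInterval(r, edges, rightmost.closed = TRUE)
  med_r <- grouped_median(bin, r)
  med_ttc <- grouped_median(bin, ttc)
  filled <- med_r$group
  med_r <- med_r$median
  med_ttc <- med_ttc$median
  # monotone in radius (PAVA); single bin passes through unchanged
  iso_ttc <- if (length(filled) > 1) stats::isoreg(med_r, med_ttc)$yf
             else med_ttc
  nbin <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  rep_r <- centers
  rep_r[filled] <- med_r
  ttc_all <- rep(NA_real_, nbin)
  ttc_all[filled] <- iso_ttc
  if (anyNA(ttc_all)) {
    ttc_all <- stats::approx(rep_r[filled], iso_ttc, xout = rep_r,
                             rule = 2)$y
  }
  ttc_all <- pmax(cummax(ttc_all), 0)   # guard interpolation round-off
  structure(list(bin_edges_m = edges, radius_m = rep_r, ttc_ms = ttc_all,
                 n_traces = length(traces)),
            class = "radius_time_map")
}

#' Analytic constant-speed time/radius map
#'
#' Cold-start map used before any run-up has been observed: time-to-contact
#' `1000 * r / speed` from uniform motion at the configured nominal speed.
#'
#' @param speed_mps Nominal run-up speed in m/s (> 0).
#' @param max_radius_m Largest radius covered (m).
#' @param bin_width_m Bin width in m.
#' @return A `radius_time_map`.
#' @export
linear_radius_time_map <- function(speed_mps, max_radius_m = 3,
                                   bin_width_m = 0.05) {
  stopifnot(speed_mps > 0, max_radius_m > 0, bin_width_m > 0)
  edges <- seq(0, max_radius_m + bin_width_m, by = bin_width_m)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(bin_edges_m = edges, radius_m = centers,
                 ttc_ms = 1000 * centers / speed_mps, n_traces = 0L),
            class = "radius_time_map")
}

#' @export
print.radius_time_map <- function(x, ...) {
  cat(sprintf(
    "Time/radius map: %d bins of %.3g m, ttc %.0f-%.0f ms, fitted from %d trace(s)\n",
    length(x$ttc_ms), diff(x$bin_edges_m[1:2]), min(x$ttc_ms), max(x$ttc_ms),
    x$n_traces))
  invisible(x)
}

#' Predicted time-to-contact at given radii
#'
#' Linear interpolation of the fitted map at the per-bin representative radii
#' (constant extrapolation beyond the covered range).
#'
#' @param object A `radius_time_map`.
#' @param radius_m Radii in m.
#' @param ... Unused.
#' @return Predicted time-to-contact in ms.
#' @export
predict.radius_time_map <- function(object, radius_m, ...) {
  stats::approx(object$radius_m, object$ttc_ms, xout = radius_m,
                rule = 2, ties = "ordered")$y
}

#' Radius at which to trigger the goalkeeper dive
#'
#' Inverts the monotone time/radius map: the radius whose predicted
#' time-to-contact equals the commanded dive lead time, by inverse linear
#' interpolation. A lead time outside the map's predicted range is an error;
#' callers that need a dive on every trial should clamp first (see
#' [clamp_tau_to_map]).
#'
#' @param map A `radius_time_map`.
#' @param tau_commanded_ms Commanded dive lead time in ms.
#' @return Radius in m.
#' @export
trigger_radius_for <- function(map, tau_commanded_ms) {
  rng <- range(map$ttc_ms)
  if (tau_commanded_ms < rng[1] || tau_commanded_ms > rng[2])
    stop(sprintf(
      "commanded lead time %.1f ms outside the map's predicted range [%.1f, %.1f] ms",
      tau_commanded_ms, rng[1], rng[2]))
  # ties = min: among radii sharing a ttc value, dive as late as possible
  stats::approx(map$ttc_ms, map$radius_m, xout = tau_commanded_ms,
                ties = min)$y
}

#' Clamp a commanded lead time into a map's predicted range
#'
#' @param map A `radius_time_map`.
#' @param tau_ms Commanded lead time in ms.
#' @return `tau_ms` clamped into `range(map$ttc_ms)`.
#' @export
clamp_tau_to_map <- function(map, tau_ms) {
  min(max(tau_ms, min(map$ttc_ms)), max(map$ttc_ms))
}

#' Simulate online triggering of the goalkeeper dive
#'
#' Scans the run-up causally, in time order, and launches the dive at the
#' first sample whose radius falls at or below the trigger radius implied by
#' the map and the commanded lead time. The realized lead time `tau_actual_ms`
#' is measured against the ground-truth contact time, mirroring how the
#' actual dive-to-contact interval is measured on court.
#'
#' @param trace A `runup_trace`.
#' @param map A `radius_time_map`.
#' @param tau_commanded_ms Commanded dive lead time in ms (must be inside the
#'   map's predicted range).
#' @return Object of class `dive_trigger`: `triggered`, `trigger_time_s`,
#'   `tau_actual_ms`, `tau_commanded_ms`.
#' @export
simulate_dive_trigger <- function(trace, map, tau_commanded_ms) {
  stopifnot(inherits(trace, "runup_trace"), inherits(map, "radius_time_map"))
  r_trig <- trigger_radius_for(map, tau_commanded_ms)
  idx <- which(trace$radius_m <= r_trig)[1]
  if (is.na(idx)) {
    return(structure(list(triggered = FALSE, trigger_time_s = NA_real_,
                          tau_actual_ms = NA_real_,
                          tau_commanded_ms = tau_commanded_ms),
                     class = "dive_trigger"))
  }
  trigger_time <- trace$t_s[idx]
  structure(list(
    triggered = TRUE, trigger_time_s = trigger_time,
    tau_actual_ms = max(0, (trace$contact_time_s - trigger_time) * 1000),
    tau_commanded_ms = tau_commanded_ms),
    class = "dive_trigger")
}
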