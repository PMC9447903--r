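#' Ergometer trace
#'
#' Container for a dual-roller wheelchair ergometer recording: per-side wheel
#' torque and linear wheel velocity sampled at a fixed rate (100 Hz on the
#' instrument), plus an optional heart-rate channel and the protocol trigger
#' `test_start` marking t = 0 of the test.
#'
#' Invariants enforced at construction: the time base is strictly increasing
#' with a constant step of 1/rate (to 1e-9 s); all channels have equal
#' length; velocities are non-negative (no backward rolling is modelled);
#' `test_start`, when given, lies within the recorded interval.
#'
#' @param torque_left,torque_right per-side wheel torque, N·m.
#' @param velocity_left,velocity_right per-side linear wheel velocity, m/s.
#' @param rate sampling rate, Hz.
#' @param time optional time vector, s; defaults to (0, 1/rate, 2/rate, ...).
#' @param heart_rate optional heart-rate channel, bpm, sampled on the trace
#'   clock (lower-rate monitors should be step-interpolated before
#'   construction; see [read_trace()]).
#' @param test_start protocol trigger time, s, or `NULL` for downstream
#'   onset detection.
#' @return an object of class `ergometer_trace`.
#' @export
ergometer_trace <- function(torque_left, torque_right, velocity_left,
                            velocity_right, rate = 100, time = NULL,
                            heart_rate = NULL, test_start = NULL) {
  n <- length(torque_left)
  if (is.null(time)) time <- (seq_len(n) - 1L) / rate
  lens <- c(length(time), length(torque_right), length(velocity_left),
            length(velocity_right))
  if (any(lens != n)) {
    stop_wheelcap("all trace channels must have equal length",
                  "wheelcap_structure_error")
  }
  if (!is.null(heart_rate) && length(heart_rate) != n) {
    stop_wheelcap("heart_rate channel length differs from trace length",
                  "wheelcap_structure_error")
  }
  if (n >= 2) {
    dt <- diff(time)
    if (any(dt <= 0) || any(abs(dt - 1 / rate) > 1e-9)) {
      bad <- which(abs(dt - 1 / rate) > 1e-9 | dt <= 0)[1] + 1L
      stop_wheelcap(
        sprintf("time base is not a uniform 1/%g s grid (first bad row: %d)",
                rate, bad),
        "wheelcap_timebase_error")
    }
  }
  if (any(velocity_left < -1e-9) || any(velocity_right < -1e-9)) {
    stop_wheelcap("negative wheel velocities are not supported",
                  "wheelcap_structure_error")
  }
  if (!is.null(test_start) &&
      (test_start < time[1] - 1e-9 || test_start > time[n] + 1e-9)) {
    stop_wheelcap("test_start lies outside the recorded interval",
                  "wheelcap_structure_error")
  }
  structure(
    list(time = as.numeric(time), rate = rate,
         torque_left = as.numeric(torque_left),
         torque_right = as.numeric(torque_right),
         velocity_left = pmax(0, as.numeric(velocity_left)),
         velocity_right = pmax(0, as.numeric(velocity_right)),
         heart_rate = if (is.null(heart_rate)) NULL else as.numeric(heart_rate),
         test_start = test_start),
    class = "ergometer_trace")
}

#' @export
print.ergometer_trace <- function(x, ...) {
  cat(sprintf("<ergometer_trace> %d samples @ %g Hz (%.2f s)%s%s\n",
              length(x$time), x$rate, length(x$time) / x$rate,
              if (is.null(x$heart_rate)) "" else ", heart rate",
              if (is.null(x$test_start)) ""
              else sprintf(", test_start = %.2f s", x$test_start)))
  invisible(x)
}

#' Wheelchair/ergometer setup
#'
#' Physical constants of a participant-wheelchair combination: masses, wheel
#' radius r_w and handrim radius r_r. These tie torque to handrim force
#' (F = M / r_r), torque and velocity to power (PO = M / r_w * v), and the
#' dimensionless rolling-resistance coefficient mu to a resistive force
#' (mu * total weight).
#'
#' @param wheelchair_mass kg.
#' @param wheel_radius r_w, m.
#' @param rim_radius r_r, m; must satisfy 0 < r_r <= r_w.
#' @param user_mass kg.
#' @param gravity m/s^2.
#' @return an object of class `wheelchair_setup` with derived `total_mass`
#'   (kg) and `total_weight` (N).
#' @export
wheelchair_setup <- function(wheelchair_mass = 10, wheel_radius = 0.34,
                             rim_radius = 0.31, user_mass, gravity = 9.81) {
  stopifnot(wheelchair_mass > 0, user_mass > 0,
            rim_radius > 0, rim_radius <= wheel_radius)
  structure(
    list(wheelchair_mass = wheelchair_mass, wheel_radius = wheel_radius,
         rim_radius = rim_radius, user_mass = user_mass, gravity = gravity,
         total_mass = wheelchair_mass + user_mass,
         total_weight = (wheelchair_mass + user_mass) * gravity),
    class = "wheelchair_setup")
}

# Zero-phase low-pass of one channel: odd-reflection padding at both ends,
# forward pass, backward pass, trim. Padding length min(n - 1, round(rate))
# samples so the zero-state start-up transient of the recursion has fully
# decayed before the retained segment.
butter_lowpass_zerophase <- function(x, rate, cutoff, order) {
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  n <- length(x)
  pad <- min(n - 1L, as.integer(round(rate)))
  front <- 2 * x[1] - x[(pad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- c(front, x, back)
  y <- as.numeric(signal::filter(bf, y))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(pad + 1L):(pad + n)]
}

#' Low-pass filter an ergometer trace
#'
#' Applies a low-pass Butterworth filter (default fourth order, 10 Hz
#' cut-off) to the torque and velocity channels. The filter is run
#' zero-phase (forward-backward over odd-reflection padded signals), so
#' window start times and peak locations are not lagged; the effective
#' attenuation order is doubled. Time base, rate, `test_start` and the
#' heart-rate channel are untouched.
#'
#' @param trace an [ergometer_trace()].
#' @param cutoff cut-off frequency, Hz; must be below the Nyquist rate.
#' @param order filter order.
#' @return the filtered `ergometer_trace`.
#' @export
filter_trace <- function(trace, cutoff = 10, order = 4) {
  stopifnot(inherits(trace, "ergometer_trace"))
  if (cutoff >= trace$rate / 2) {
    stop_wheelcap("cutoff must be below the Nyquist frequency rate/2",
                  "wheelcap_config_error")
  }
  if (length(trace$time) < 3 * (order + 1)) {
    stop_wheelcap("trace too short for edge padding (need >= 3*(order+1) samples)",
                  "wheelcap_short_signal_error")
  }
  for (ch in c("torque_left", "torque_right", "velocity_left", "velocity_right")) {
    trace[[ch]] <- butter_lowpass_zerophase(trace[[ch]], trace$rate, cutoff, order)
  }
  trace$velocity_left <- pmax(0, trace$velocity_left)
  trace$velocity_right <- pmax(0, trace$velocity_right)
  trace
}
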