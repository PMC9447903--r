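#' Convert torque/velocity to handrim force and power output
#'
#' Per side, the effective tangential handrim force is F = M / r_r and the
#' power output is PO = (M / r_w) * v, with M the wheel torque, r_r the
#' handrim radius, r_w the wheel radius and v the linear wheel velocity.
#' The aggregates follow the field's conventions: force is reported as the
#' average of both arms, power as the sum of both arms, velocity as the
#' average of both sides.
#'
#' @param trace an [ergometer_trace()], normally already passed through
#'   [filter_trace()].
#' @param setup a [wheelchair_setup()].
#' @return an object of class `force_power_trace` with per-side
#'   `force_left/right` (N), `power_left/right` (W) and aggregates
#'   `force_mean` (N), `power_total` (W), `velocity_mean` (m/s); `time`,
#'   `rate`, `heart_rate` and `test_start` carried over.
#' @export
compute_force_power <- function(trace, setup) {
  stopifnot(inherits(trace, "ergometer_trace"),
            inherits(setup, "wheelchair_setup"))
  fl <- trace$torque_left / setup$rim_radius
  fr <- trace$torque_right / setup$rim_radius
  pl <- trace$torque_left / setup$wheel_radius * trace$velocity_left
  pr <- trace$torque_right / setup$wheel_radius * trace$velocity_right
  structure(
    list(time = trace$time, rate = trace$rate,
         force_left = fl, force_right = fr,
         power_left = pl, power_right = pr,
         force_mean = (fl + fr) / 2,
         power_total = pl + pr,
         velocity_mean = (trace$velocity_left + trace$velocity_right) / 2,
         heart_rate = trace$heart_rate,
         test_start = trace$test_start,
         setup = setup),
    class = "force_power_trace")
}

#' @export
print.force_power_trace <- function(x, ...) {
  cat(sprintf("<force_power_trace> %d samples @ %g Hz (%.2f s)\n",
              length(x$time), x$rate, length(x$time) / x$rate))
  invisible(x)
}

#' Maximum rolling-window mean
#'
#' Shared kernel for every windowed outcome of the protocol (3 s isometric
#' strength window, 5 s Wingate intervals, 30 s GXT peak-power window).
#' Windows are sample-count windows of round(window * rate) samples, full
#' windows only, stride one sample; ties are broken to the earliest window.
#'
#' @param x numeric signal sampled at `rate`.
#' @param window window length, s.
#' @param rate sampling rate, Hz.
#' @return list with `value` (the maximal window mean), `start_index`
#'   (1-based index of the first sample of the earliest maximising window)
#'   and `start_time` ((start_index - 1)/rate, i.e. relative to the first
#'   sample of `x`).
#' @export
rolling_mean_max <- function(x, window, rate) {
  w <- as.integer(round(window * rate))
  if (w < 1L) {
    stop_wheelcap("window shorter than one sample", "wheelcap_config_error")
  }
  n <- length(x)
  if (n < w) {
    stop_wheelcap("signal shorter than one window",
                  "wheelcap_insufficient_data_error")
  }
  cs <- c(0, cumsum(x))
  means <- (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
  i <- which.max(means)
  list(value = means[i], start_index = i, start_time = (i - 1L) / rate)
}

#' Locate the start of a test within a trace
#'
#' Returns the trace's recorded `test_start` when present; otherwise an
#' onset rule is applied: the first sample where the side-averaged velocity
#' exceeds 0.1 m/s, or — for isometric tests, where the wheels never move —
#' the first sample where the side-averaged handrim force exceeds 5 N.
#'
#' @param fp a `force_power_trace`.
#' @param type `"dynamic"` (velocity onset) or `"isometric"` (force onset).
#' @return start time in seconds on the trace clock.
#' @export
detect_test_start <- function(fp, type = c("dynamic", "isometric")) {
  if (!is.null(fp$test_start)) return(fp$test_start)
  type <- match.arg(type)
  i <- if (type == "isometric") which(fp$force_mean > 5)[1]
       else which(fp$velocity_mean > 0.1)[1]
  if (is.na(i)) {
    stop_wheelcap("no test onset detectable and no test_start recorded",
                  "wheelcap_insufficient_data_error")
  }
  fp$time[i]
}

# Index of the first sample at or after the test start.
start_index <- function(fp, type = "dynamic") {
  ts <- detect_test_start(fp, type)
  i <- which(fp$time >= ts - 1e-9)[1]
  if (is.na(i)) {
    stop_wheelcap("test_start beyond end of trace",
                  "wheelcap_insufficient_data_error")
  }
  i
}
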