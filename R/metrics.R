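#' Isometric strength outcome (F_iso)
#'
#' Maximal isometric handrim strength: per trial, the highest 3 s rolling
#' mean of the side-averaged handrim force after the test start; across up
#' to three 5 s trials, the best trial wins. Trials shorter than one 3 s
#' window are flagged unusable and dropped; if no usable trial remains
#' (e.g. the participant pushed through the ergometer brakes and the trial
#' could not be recorded), a `wheelcap_no_result_error` is signalled.
#'
#' @param trials list of `force_power_trace` objects, one per trial.
#' @param user_mass participant body mass, kg, for the per-kg value.
#' @param window rolling window, s.
#' @return an `isometric_result`: `f_iso` (N), `f_iso_per_kg` (N/kg),
#'   `trial_values` (N, `NA` for unusable trials), `n_trials`.
#' @export
isometric_strength <- function(trials, user_mass, window = 3) {
  if (inherits(trials, "force_power_trace")) trials <- list(trials)
  stopifnot(length(trials) >= 1, user_mass > 0)
  vals <- vapply(trials, function(fp) {
    i0 <- tryCatch(start_index(fp, "isometric"), error = function(e) NA_integer_)
    if (is.na(i0)) return(NA_real_)
    seg <- fp$force_mean[i0:length(fp$force_mean)]
    if (length(seg) < round(window * fp$rate)) return(NA_real_)
    rolling_mean_max(seg, window, fp$rate)$value
  }, numeric(1))
  if (all(is.na(vals))) {
    stop_wheelcap("no usable isometric trial (all shorter than the window)",
                  "wheelcap_no_result_error")
  }
  f_iso <- max(vals, na.rm = TRUE)
  structure(list(f_iso = f_iso, f_iso_per_kg = f_iso / user_mass,
                 trial_values = vals, n_trials = length(trials)),
            class = "isometric_result")
}

#' Sprint test outcomes
#'
#' For each 10 s sprint: mean power output (sum of both arms) and mean
#' velocity (side average) over the 10 s from the test start, plus the
#' one-sample peaks within that window. The sprint with the highest
#' `v_max` is retained for further analysis.
#'
#' @param sprints a `force_power_trace` or list of them (typically two).
#' @param duration analysis window, s.
#' @return a `sprint_result`: `po_mean`, `po_max` (W), `v_mean`, `v_max`
#'   (m/s), `sprint_used` (index of the retained sprint).
#' @export
sprint_outcomes <- function(sprints, duration = 10) {
  if (inherits(sprints, "force_power_trace")) sprints <- list(sprints)
  per <- lapply(sprints, function(fp) {
    i0 <- start_index(fp, "dynamic")
    w <- as.integer(round(duration * fp$rate))
    if (length(fp$time) - i0 + 1L < w) return(NULL)
    idx <- i0:(i0 + w - 1L)
    list(po_mean = mean(fp$power_total[idx]),
         po_max = max(fp$power_total[idx]),
         v_mean = mean(fp$velocity_mean[idx]),
         v_max = max(fp$velocity_mean[idx]))
  })
  ok <- !vapply(per, is.null, logical(1))
  if (!any(ok)) {
    stop_wheelcap("no sprint long enough for the analysis window",
                  "wheelcap_insufficient_data_error")
  }
  vmax <- vapply(per, function(p) if (is.null(p)) -Inf else p$v_max, numeric(1))
  best <- which.max(vmax)
  structure(c(per[[best]], list(sprint_used = best)), class = "sprint_result")
}

#' Wingate (WAnT) outcomes
#'
#' From a 30 s all-out test: P30 (mean summed power over the 30 s from the
#' test start), the six successive 5 s interval means, P5 (their maximum),
#' the one-sample power peak, and the rate of fatigue
#' RF = (P5_first - P5_last) / P5_first * 100 with P5_first/P5_last the
#' first and last of the six interval means. Velocity outcomes are the
#' side-averaged mean over 30 s and the one-sample peak.
#'
#' @param fp a `force_power_trace` of the Wingate test.
#' @param duration test duration, s.
#' @param interval fatigue-interval length, s.
#' @return a `wingate_result`: `p30`, `p5`, `po_max` (W), `rf` (%),
#'   `v_mean`, `v_max` (m/s), `p5_intervals` (W).
#' @export
wingate_outcomes <- function(fp, duration = 30, interval = 5) {
  i0 <- start_index(fp, "dynamic")
  w <- as.integer(round(duration * fp$rate))
  if (length(fp$time) - i0 + 1L < w) {
    stop_wheelcap("trace shorter than the Wingate window",
                  "wheelcap_insufficient_data_error")
  }
  idx <- i0:(i0 + w - 1L)
  po <- fp$power_total[idx]
  v <- fp$velocity_mean[idx]
  k <- as.integer(round(interval * fp$rate))
  n_int <- w %/% k
  p5_int <- colMeans(matrix(po[1:(n_int * k)], nrow = k))
  if (p5_int[1] <= 0) {
    stop_wheelcap("first interval mean power is non-positive; rate of fatigue undefined",
                  "wheelcap_degenerate_trace_error")
  }
  structure(
    list(p30 = mean(po), p5 = max(p5_int), po_max = max(po),
         rf = (p5_int[1] - p5_int[n_int]) / p5_int[1] * 100,
         v_mean = mean(v), v_max = max(v), p5_intervals = p5_int),
    class = "wingate_result")
}

#' Graded exercise test (GXT) outcomes
#'
#' POpeak is the highest mean summed power achieved over any 30 s window
#' between the test start and termination (the trace ends when the
#' participant can no longer hold the target velocity). Duration is
#' last-sample time minus test start; HR_peak is the one-sample maximum of
#' the heart-rate channel (absent channel gives `NA`, secondary validity
#' checks then degrade gracefully). The overall RPE is the half-up-rounded
#' average of the central and peripheral ratings (1-10).
#'
#' @param fp a `force_power_trace` of the GXT.
#' @param rpe_central,rpe_peripheral post-test ratings of perceived
#'   exertion, integers 1-10 (cardiorespiratory / exercising muscles).
#' @param window POpeak window, s.
#' @return a `gxt_result`: `po_peak` (W), `duration` (s), `hr_peak` (bpm or
#'   `NA`), `rpe_central`, `rpe_peripheral`, `rpe_overall`,
#'   `completed_stages` (informational, floor(duration / 60)).
#' @export
gxt_outcomes <- function(fp, rpe_central = NA, rpe_peripheral = NA,
                         window = 30) {
  i0 <- start_index(fp, "dynamic")
  n <- length(fp$time)
  w <- as.integer(round(window * fp$rate))
  if (n - i0 + 1L < w) {
    stop_wheelcap("trace shorter than the POpeak window",
                  "wheelcap_insufficient_data_error")
  }
  for (r in c(rpe_central, rpe_peripheral)) {
    if (!is.na(r) && (r < 1 || r > 10)) {
      stop_wheelcap("RPE ratings must lie in 1-10", "wheelcap_config_error")
    }
  }
  po_peak <- rolling_mean_max(fp$power_total[i0:n], window, fp$rate)$value
  duration <- fp$time[n] - fp$time[i0]
  hr_peak <- if (is.null(fp$heart_rate)) NA_real_
             else max(fp$heart_rate[i0:n], na.rm = TRUE)
  rpe_overall <- if (is.na(rpe_central) || is.na(rpe_peripheral)) NA_real_
                 else round_half_up((rpe_central + rpe_peripheral) / 2)
  structure(
    list(po_peak = po_peak, duration = duration, hr_peak = hr_peak,
         rpe_central = rpe_central, rpe_peripheral = rpe_peripheral,
         rpe_overall = rpe_overall,
         completed_stages = floor(duration / 60)),
    class = "gxt_result")
}
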