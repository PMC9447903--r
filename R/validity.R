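#' Wingate validity
#'
#' A Wingate test is valid when the resistance allowed proper hand-rim
#' coordination: the one-sample maximal velocity must not exceed 3 m/s
#' (3.00 is valid, 3.01 is not), and the participant must have been able to
#' accelerate against the resistance at all (mean velocity above a small
#' threshold).
#'
#' @param result a `wingate_result` or anything with `v_max`/`v_mean`.
#' @param v_limit maximal allowed one-sample velocity, m/s.
#' @param min_v_mean minimal mean velocity evidencing acceleration, m/s.
#' @return list with `valid` and `reason` (`NA` when valid).
#' @export
validate_wingate <- function(result, v_limit = 3.0, min_v_mean = 0.5) {
  if (result$v_max > v_limit + 1e-9) {
    return(list(valid = FALSE,
                reason = sprintf("v_max %.2f m/s exceeds %.1f m/s", result$v_max, v_limit)))
  }
  if (!is.na(result$v_mean) && result$v_mean <= min_v_mean) {
    return(list(valid = FALSE,
                reason = "participant could not accelerate against the resistance"))
  }
  list(valid = TRUE, reason = NA_character_)
}

#' GXT validity
#'
#' The primary criterion is test duration: a GXT is valid when exhaustion
#' occurred between 8 and 12 min inclusive (480-720 s). Secondary criteria
#' indicate whether a true maximal effort was approached: a peak heart rate
#' of at least 95% of the age-predicted maximum (200 - age), with the
#' threshold rounded half-up to whole bpm, and an overall RPE of at least
#' 8. Missing HR or RPE leaves the corresponding flag `NA`; the duration
#' criterion is always evaluated and alone determines `gxt_valid`.
#'
#' @param result a `gxt_result` (or anything with `duration`, `hr_peak`,
#'   `rpe_overall`).
#' @param age participant age, years.
#' @param min_duration,max_duration valid duration bounds, s (inclusive).
#' @return a `validity_report`: `gxt_duration_valid`, `gxt_hr_valid`,
#'   `gxt_rpe_valid`, `gxt_valid`, `hr_threshold`.
#' @export
validate_gxt <- function(result, age = NA, min_duration = 480,
                         max_duration = 720) {
  dur_ok <- result$duration >= min_duration & result$duration <= max_duration
  hr_thr <- if (is.na(age)) NA_real_ else round_half_up(0.95 * (200 - age))
  hr_ok <- if (is.na(age) || is.na(result$hr_peak)) NA
           else result$hr_peak >= hr_thr
  rpe_ok <- if (is.na(result$rpe_overall)) NA else result$rpe_overall >= 8
  structure(
    list(gxt_duration_valid = dur_ok, gxt_hr_valid = hr_ok,
         gxt_rpe_valid = rpe_ok, gxt_valid = dur_ok, hr_threshold = hr_thr),
    class = "validity_report")
}
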