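#' Estimate the Wingate outcome from isometric strength
#'
#' Applies the published regression between per-kg isometric strength and
#' per-kg 30 s mean power, P30_est \[W/kg\] = 0.51 * F_iso \[N/kg\] - 0.18,
#' and scales back to absolute watts with the user's body mass. Estimates
#' are kept at full precision; round for display with [round_half_up()].
#'
#' @param f_iso isometric strength, N (side average).
#' @param user_mass body mass, kg.
#' @return list with `p30_est_per_kg` (W/kg), `p30_est` (W) and `flagged`
#'   (`TRUE` when the estimate is non-positive, in which case no Wingate
#'   resistance can be prescribed).
#' @export
estimate_p30 <- function(f_iso, user_mass) {
  stopifnot(f_iso > 0, user_mass > 0)
  per_kg <- 0.51 * (f_iso / user_mass) - 0.18
  list(p30_est_per_kg = per_kg, p30_est = per_kg * user_mass,
       flagged = per_kg <= 0)
}

#' Individualized Wingate resistance
#'
#' Converts the estimated 30 s mean power into the ergometer's rolling
#' resistance coefficient so that the test is ridden at a target mean
#' velocity (2 m/s, chosen to stay below the 3 m/s coordination limit):
#' mu = P30_est / (v_target * m_total * g), i.e. the estimated power
#' divided by target velocity gives the required resistive force, which is
#' expressed relative to total weight.
#'
#' @param p30_est estimated 30 s mean power, W (sum of both arms).
#' @param setup a [wheelchair_setup()].
#' @param target_v target mean velocity, m/s.
#' @return a `want_prescription`: `p30_est`, `p30_est_per_kg`, `target_v`,
#'   `mu`.
#' @export
wingate_resistance <- function(p30_est, setup, target_v = 2.0) {
  stopifnot(inherits(setup, "wheelchair_setup"), target_v > 0)
  if (p30_est <= 0) {
    stop_wheelcap("non-positive P30 estimate: no Wingate resistance can be prescribed",
                  "wheelcap_no_result_error")
  }
  structure(
    list(p30_est = p30_est, p30_est_per_kg = p30_est / setup$user_mass,
         target_v = target_v,
         mu = p30_est / (target_v * setup$total_weight)),
    class = "want_prescription")
}

#' Estimate the GXT outcome from the measured Wingate outcome
#'
#' Applies the published regression between per-kg 30 s mean power and
#' per-kg peak aerobic power, POpeak_est \[W/kg\] = 0.67 * P30 \[W/kg\] + 0.11.
#'
#' @param p30_meas measured 30 s mean power, W (sum of both arms).
#' @param user_mass body mass, kg.
#' @return list with `po_peak_est_per_kg` (W/kg) and `po_peak_est` (W).
#' @export
estimate_popeak <- function(p30_meas, user_mass) {
  stopifnot(p30_meas >= 0, user_mass > 0)
  per_kg <- 0.67 * (p30_meas / user_mass) + 0.11
  list(po_peak_est_per_kg = per_kg, po_peak_est = per_kg * user_mass)
}

#' Individualized GXT stage schedule
#'
#' Minute-wise incremental schedule at constant velocity (1.39 m/s): the
#' first stage requires 20% of POpeak_est and every subsequent one-minute
#' stage adds 10% of the difference between the starting load and
#' POpeak_est, i.e. 8% of POpeak_est per minute. Stage 11 therefore
#' requires exactly 100%, so a participant whose capacity equals the
#' estimate reaches their peak at around 10 min. Per-stage resistance
#' coefficients follow the constant-velocity power balance
#' mu_n = P_n / (v * m_total * g). More stages than 11 are scheduled so
#' over-performing participants remain representable.
#'
#' @param po_peak_est estimated peak aerobic power, W.
#' @param setup a [wheelchair_setup()].
#' @param n_stages number of scheduled one-minute stages.
#' @param velocity constant target velocity, m/s.
#' @param start_frac,increment_frac schedule fractions of `po_peak_est`.
#' @return a `gxt_schedule`: `po_peak_est`, `stage_powers` (W),
#'   `stage_mus`, `constant_velocity`, `stage_duration` (s).
#' @export
gxt_schedule <- function(po_peak_est, setup, n_stages = 15, velocity = 1.39,
                         start_frac = 0.20, increment_frac = 0.08) {
  stopifnot(inherits(setup, "wheelchair_setup"), po_peak_est > 0,
            n_stages >= 1)
  frac <- start_frac + increment_frac * (seq_len(n_stages) - 1)
  powers <- po_peak_est * frac
  structure(
    list(po_peak_est = po_peak_est, stage_powers = powers,
         stage_mus = powers / (velocity * setup$total_weight),
         constant_velocity = velocity, stage_duration = 60),
    class = "gxt_schedule")
}
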