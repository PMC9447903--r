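#' Simulation configuration
#'
#' Bundles everything the trace generator needs: RNG seed, sampling rate,
#' sensor and latent noise levels, the wheelchair geometry and the protocol
#' parameters. Identical seed + config give bit-identical cohorts and
#' traces.
#'
#' Latent-noise defaults reflect the spread observed in a novice
#' able-bodied cohort: `sigma1`/`sigma2` (W/kg) are the residual SDs of the
#' anaerobic-on-strength and aerobic-on-anaerobic relations, sized so the
#' generated cohort reproduces explained variances of roughly 0.8 and 0.67.
#'
#' @param seed integer RNG seed.
#' @param rate sampling rate, Hz.
#' @param torque_sd torque sensor noise SD, N·m.
#' @param sigma1 residual SD of latent P30/kg about 0.51 * F_iso/kg - 0.18.
#' @param sigma2 residual SD of latent POpeak/kg about 0.67 * P30/kg + 0.11.
#' @param endurance_sd SD of the multiplicative day-to-day jitter on GXT
#'   endurance capacity (dimensionless).
#' @param wheelchair_mass,wheel_radius,rim_radius wheelchair geometry
#'   (tennis-wheelchair defaults: 10 kg, 0.34 m, 0.31 m).
#' @param sprint_mu rolling-resistance coefficient of the sprint test
#'   (gym-court value).
#' @param want_target_v Wingate target mean velocity, m/s.
#' @param gxt_velocity GXT constant target velocity, m/s.
#' @param sprint_ratio ratio of 10 s sprint mean power to P30.
#' @param iso_tau force rise time constant of the isometric effort, s.
#' @param fail_duration seconds of decaying velocity appended when a GXT
#'   stage exceeds capacity.
#' @param hr_tau heart-rate response time constant, s.
#' @param v_limit limiting hand/rim speed of the force-velocity relation,
#'   m/s: deliverable push force falls linearly with rim speed and
#'   vanishes here, which is what bounds all-out velocities in reality.
#' @param n_iso_trials,n_sprints repetitions of the first two tests.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, rate = 100, torque_sd = 0.1,
                       sigma1 = 0.17, sigma2 = 0.11, endurance_sd = 0.05,
                       wheelchair_mass = 10, wheel_radius = 0.34,
                       rim_radius = 0.31, sprint_mu = 0.012,
                       want_target_v = 2.0, gxt_velocity = 1.39,
                       sprint_ratio = 0.72, iso_tau = 0.3,
                       fail_duration = 8, hr_tau = 30, v_limit = 4,
                       n_iso_trials = 3, n_sprints = 2) {
  structure(as.list(environment()), class = "sim_config")
}

#' Noise-free simulation configuration
#'
#' All sensor and latent noise amplitudes zero: extracted outcomes then
#' equal the generating latent capacities up to integration error, which is
#' the regime in which the protocol's design properties (target Wingate
#' velocity, around-10-min GXT) hold exactly.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_noise_free <- function(...) {
  sim_config(torque_sd = 0, sigma1 = 0, sigma2 = 0, endurance_sd = 0, ...)
}

setup_for <- function(p, config) {
  wheelchair_setup(wheelchair_mass = config$wheelchair_mass,
                   wheel_radius = config$wheel_radius,
                   rim_radius = config$rim_radius,
                   user_mass = p$body_mass)
}

#' Construct a participant model
#'
#' Latent capacities are per-kg; absolute values are obtained with the body
#' mass. Used directly for designed test cases and by [generate_cohort()].
#'
#' @param id identifier.
#' @param sex `"F"` or `"M"`.
#' @param age years.
#' @param body_mass kg.
#' @param f_iso_per_kg latent isometric strength, N/kg.
#' @param p30_per_kg latent 30 s anaerobic power, W/kg; default follows the
#'   generating relation 0.51 * f_iso_per_kg - 0.18 exactly.
#' @param po_peak_per_kg latent peak aerobic power, W/kg; default follows
#'   0.67 * p30_per_kg + 0.11 exactly.
#' @param hr_rest,hr_max resting and maximal heart rate, bpm.
#' @param push_frequency push cadence, Hz.
#' @param fatigue_rate fraction of push amplitude lost over the 30 s
#'   Wingate.
#' @param endurance_jitter multiplicative deviation of GXT endurance
#'   capacity from latent POpeak.
#' @param sprint_ratio sprint mean power as a fraction of latent P30.
#' @return a `participant_model`.
#' @export
make_participant <- function(id = 1L, sex = "F", age = 23, body_mass = 72,
                             f_iso_per_kg = 2.9,
                             p30_per_kg = 0.51 * f_iso_per_kg - 0.18,
                             po_peak_per_kg = 0.67 * p30_per_kg + 0.11,
                             hr_rest = 65, hr_max = 200 - age,
                             push_frequency = 1.0, fatigue_rate = 0.55,
                             endurance_jitter = 0, sprint_ratio = 0.72) {
  stopifnot(body_mass > 0, f_iso_per_kg > 0, p30_per_kg > 0,
            po_peak_per_kg > 0)
  structure(as.list(environment()), class = "participant_model")
}

#' Generate a synthetic cohort
#'
#' Draws `n` participants from population distributions matching a young
#' able-bodied novice cohort (age 23 +/- 2 y, body mass 72 +/- 11 kg,
#' F_iso 2.9 +/- 0.8 N/kg), with latent anaerobic and aerobic capacities
#' generated from the scaling relations P30/kg = 0.51 * F_iso/kg - 0.18 +
#' e1 and POpeak/kg = 0.67 * P30/kg + 0.11 + e2 (e1 ~ N(0, sigma1), e2 ~
#' N(0, sigma2)); non-positive latent capacities are rejection-resampled.
#'
#' @param n cohort size.
#' @param config a [sim_config()]; `config$seed` makes the draw
#'   deterministic.
#' @return list of `participant_model` objects.
#' @export
generate_cohort <- function(n, config = sim_config()) {
  stopifnot(n >= 1)
  set.seed(config$seed)
  draw_pos <- function(mean, sd, lower = 0) {
    x <- stats::rnorm(1, mean, sd)
    while (x <= lower) x <- stats::rnorm(1, mean, sd)
    x
  }
  lapply(seq_len(n), function(i) {
    sex <- sample(c("F", "M"), 1)
    age <- round(min(30, max(18, stats::rnorm(1, 23, 2))))
    mass <- draw_pos(72, 11, lower = 40)
    f_iso <- draw_pos(2.9, 0.8, lower = 0.3)
    p30 <- if (config$sigma1 == 0) 0.51 * f_iso - 0.18
           else {
             x <- 0.51 * f_iso - 0.18 + stats::rnorm(1, 0, config$sigma1)
             while (x <= 0.05) x <- 0.51 * f_iso - 0.18 + stats::rnorm(1, 0, config$sigma1)
             x
           }
    popeak <- if (config$sigma2 == 0) 0.67 * p30 + 0.11
              else {
                x <- 0.67 * p30 + 0.11 + stats::rnorm(1, 0, config$sigma2)
                while (x <= 0.05) x <- 0.67 * p30 + 0.11 + stats::rnorm(1, 0, config$sigma2)
                x
              }
    make_participant(
      id = i, sex = sex, age = age, body_mass = mass,
      f_iso_per_kg = f_iso, p30_per_kg = p30, po_peak_per_kg = popeak,
      hr_rest = round(draw_pos(65, 7, lower = 40)),
      hr_max = 200 - age,
      push_frequency = draw_pos(1.0, 0.1, lower = 0.6),
      fatigue_rate = min(0.7, max(0.35, stats::rnorm(1, 0.55, 0.07))),
      endurance_jitter = if (config$endurance_sd == 0) 0
                         else stats::rnorm(1, 0, config$endurance_sd),
      sprint_ratio = config$sprint_ratio)
  })
}

#' Ground-truth latents of a cohort
#'
#' @param cohort list of `participant_model` objects.
#' @return data frame of the latent per-kg capacities, for parameter
#'   recovery checks.
#' @export
cohort_truth <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(id = p$id, sex = p$sex, age = p$age, body_mass = p$body_mass,
               f_iso_per_kg = p$f_iso_per_kg, p30_per_kg = p$p30_per_kg,
               po_peak_per_kg = p$po_peak_per_kg)
  }))
}

# Forward dynamics of roller propulsion: the summed handrim force F_hand(t)
# produces a drive force F_hand * r_r / r_w at the roller surface, opposed
# by the constant resistive force mu * total weight while the wheels turn.
# The deliverable push force falls linearly with hand (= rim = wheel)
# speed, vanishing at the coordination/contraction limit v_lim — the
# force-velocity property that in reality keeps all-out rim speeds
# bounded. Velocity is Euler-integrated at the sampling rate and clamped
# at zero (the ergometer does not roll backwards).
propel_dynamics <- function(f_hand_sum, rate, mu, setup, v_lim = 4) {
  n <- length(f_hand_sum)
  dt <- 1 / rate
  f_drive <- f_hand_sum * setup$rim_radius / setup$wheel_radius
  resist <- mu * setup$total_weight
  m <- setup$total_mass
  v <- numeric(n)
  fd <- numeric(n)
  vi <- 0
  for (i in seq_len(n)) {
    v[i] <- vi
    fd[i] <- f_drive[i] * max(0, 1 - vi / v_lim)
    vi <- max(0, vi + (fd[i] - resist) / m * dt)
  }
  list(velocity = v, power = fd * v, f_drive = fd)
}

# Half-rectified sinusoidal push profile with linear amplitude fade.
push_profile <- function(amp, freq, fade, duration, rate) {
  t <- (seq_len(round(duration * rate)) - 1L) / rate
  amp * pmax(0, sin(2 * pi * freq * t)) * (1 - fade * t / duration)
}

# Calibrate the push amplitude so the realized mean summed power over the
# trace equals `target_power`. Mean power is continuous and increasing in
# the amplitude, but saturates: the force-velocity relation bounds the
# power attainable against a given resistance, and the push force itself
# is bounded by `a_max` (N, summed over both arms). When the target is
# unreachable the behaviour depends on `saturate`: return the maximal
# amplitude (the realized power then falls short of the target, as happens
# in a sprint at gym-court resistance) or signal an infeasible
# participant/prescription pair.
calibrate_amplitude <- function(target_power, freq, fade, duration, rate,
                                mu, setup, v_lim = 4, a_max = 2000,
                                saturate = FALSE) {
  mean_power <- function(a) {
    f <- push_profile(a, freq, fade, duration, rate)
    mean(propel_dynamics(f, rate, mu, setup, v_lim)$power)
  }
  lo <- 1e-3
  hi <- min(a_max, max(50, 4 * target_power))
  while (mean_power(hi) < target_power && hi < a_max) {
    hi <- min(a_max, hi * 2)
  }
  if (mean_power(hi) < target_power) {
    if (saturate) return(hi)
    stop_wheelcap("push amplitude calibration failed to bracket the target power",
                  "wheelcap_calibration_error")
  }
  stats::uniroot(function(a) mean_power(a) - target_power,
                 lower = lo, upper = hi, tol = 1e-7)$root
}

trace_from_dynamics <- function(dyn, rate, config) {
  n <- length(dyn$f_drive)
  # delivered drive force back to per-side wheel torque (M = F_drive * r_w)
  m_side <- dyn$f_drive / 2 * config$wheel_radius
  noise <- function() if (config$torque_sd > 0) stats::rnorm(n, 0, config$torque_sd) else 0
  ergometer_trace(
    torque_left = m_side + noise(), torque_right = m_side + noise(),
    velocity_left = dyn$velocity, velocity_right = dyn$velocity,
    rate = rate, test_start = 0)
}

#' Simulate an isometric strength trial
#'
#' 5 s trace with blocked wheels (velocity identically zero): each arm's
#' handrim force rises with a first-order response (time constant
#' `config$iso_tau`) to a plateau equal to the participant's latent
#' strength, plus torque sensor noise. The 3 s rolling-mean extraction
#' therefore recovers the latent F_iso to well within 1% in the noise-free
#' limit.
#'
#' @param p a `participant_model`.
#' @param config a [sim_config()].
#' @param duration trial length, s.
#' @return an [ergometer_trace()].
#' @export
simulate_isometric <- function(p, config = sim_config(), duration = 5) {
  n <- round(duration * config$rate)
  t <- (seq_len(n) - 1L) / config$rate
  f_side <- p$f_iso_per_kg * p$body_mass * (1 - exp(-t / config$iso_tau))
  m_side <- f_side * config$rim_radius
  noise <- function() if (config$torque_sd > 0) stats::rnorm(n, 0, config$torque_sd) else 0
  ergometer_trace(
    torque_left = m_side + noise(), torque_right = m_side + noise(),
    velocity_left = numeric(n), velocity_right = numeric(n),
    rate = config$rate, test_start = 0)
}

#' Simulate a 10 s sprint test
#'
#' From a stationary start against the gym-court rolling resistance
#' (mu = 0.012), with a half-rectified sinusoidal push profile whose
#' amplitude is calibrated so the realized 10 s mean summed power equals
#' the participant's sprint capacity (`sprint_ratio` * latent absolute
#' P30), or saturates below it for strong participants whose capacity is
#' unattainable at such a low resistance (speed, not force, then limits
#' the sprint — as observed on real ergometers).
#'
#' @param p a `participant_model`.
#' @param config a [sim_config()].
#' @param duration s.
#' @param mu rolling-resistance coefficient.
#' @return an [ergometer_trace()].
#' @export
simulate_sprint <- function(p, config = sim_config(), duration = 10,
                            mu = config$sprint_mu) {
  setup <- setup_for(p, config)
  target <- p$sprint_ratio * p$p30_per_kg * p$body_mass
  amp <- calibrate_amplitude(target, p$push_frequency, fade = 0,
                             duration, config$rate, mu, setup,
                             config$v_limit, saturate = TRUE)
  f <- push_profile(amp, p$push_frequency, 0, duration, config$rate)
  dyn <- propel_dynamics(f, config$rate, mu, setup, config$v_limit)
  trace_from_dynamics(dyn, config$rate, config)
}

#' Simulate a 30 s Wingate test
#'
#' All-out effort from a stationary start against the prescribed
#' individualized resistance. The push amplitude fades linearly by the
#' participant's `fatigue_rate` over the 30 s and is calibrated by root
#' finding against the integrator so the realized 30 s mean summed power
#' equals the latent absolute P30 (within the calibration tolerance,
#' i.e. well under 0.5% noise-free).
#'
#' @param p a `participant_model`.
#' @param prescription a [wingate_resistance()] prescription.
#' @param config a [sim_config()].
#' @param duration s.
#' @return an [ergometer_trace()].
#' @export
simulate_wingate <- function(p, prescription, config = sim_config(),
                             duration = 30) {
  stopifnot(inherits(prescription, "want_prescription"))
  if (prescription$mu <= 0) {
    stop_wheelcap("non-positive prescribed resistance", "wheelcap_config_error")
  }
  setup <- setup_for(p, config)
  target <- p$p30_per_kg * p$body_mass
  amp <- calibrate_amplitude(target, p$push_frequency, p$fatigue_rate,
                             duration, config$rate, prescription$mu, setup,
                             config$v_limit)
  f <- push_profile(amp, p$push_frequency, p$fatigue_rate, duration,
                    config$rate)
  dyn <- propel_dynamics(f, config$rate, prescription$mu, setup,
                         config$v_limit)
  trace_from_dynamics(dyn, config$rate, config)
}

#' Simulate a graded exercise test
#'
#' The participant holds the schedule's constant target velocity through
#' every one-minute stage whose required power is strictly below their
#' endurance capacity (latent POpeak * (1 + endurance_jitter)); exhaustion
#' occurs at the first stage whose requirement reaches capacity — one
#' cannot sustain a full minute at one's peak — after which the velocity
#' decays to zero within `config$fail_duration` seconds and the trace
#' ends. Heart rate follows a first-order response (time constant
#' `config$hr_tau`) from rest towards rest + (max - rest) * (required
#' power / latent POpeak), saturating at `hr_max`. RPE ratings are drawn
#' as discretized normals (central ~ N(7, 1), peripheral ~ N(9, 1),
#' clipped to 1-10), matching the novice pattern of predominantly
#' peripheral exertion.
#'
#' @param p a `participant_model`.
#' @param schedule a [gxt_schedule()].
#' @param config a [sim_config()].
#' @return list with `trace` (an [ergometer_trace()] including heart
#'   rate), `rpe_central`, `rpe_peripheral`, and `exhausted` (`FALSE` when
#'   the schedule ran out before capacity was reached).
#' @export
simulate_gxt <- function(p, schedule, config = sim_config()) {
  stopifnot(inherits(schedule, "gxt_schedule"))
  capacity <- p$po_peak_per_kg * p$body_mass * (1 + p$endurance_jitter)
  v0 <- schedule$constant_velocity
  rate <- config$rate
  n_stage <- round(schedule$stage_duration * rate)
  # a stage is only sustainable strictly below capacity (with a 0.1%
  # margin): exhaustion occurs during the stage at which the requirement
  # reaches one's peak, so that peak power is met at, not after, failure
  sustained <- schedule$stage_powers < capacity * (1 - 1e-3)
  k <- if (all(sustained)) length(sustained) + 1L else which(!sustained)[1]
  exhausted <- k <= length(schedule$stage_powers)

  p_req <- rep(schedule$stage_powers[seq_len(k - 1L)], each = n_stage)
  v <- rep(v0, length(p_req))
  if (exhausted) {
    n_fail <- round(config$fail_duration * rate)
    v_fail <- v0 * (1 - seq_len(n_fail) / n_fail)
    # during collapse the participant still pushes at capacity force
    p_fail <- capacity * v_fail / v0
    p_req <- c(p_req, p_fail)
    v <- c(v, v_fail)
  }
  n <- length(p_req)
  if (n == 0) {
    stop_wheelcap("empty schedule", "wheelcap_config_error")
  }
  # torque per side from the delivered power at the instantaneous velocity
  f_drive <- ifelse(v > 0, p_req / pmax(v, 1e-9), 0)
  m_side <- f_drive / 2 * config$wheel_radius
  noise <- function() if (config$torque_sd > 0) stats::rnorm(n, 0, config$torque_sd) else 0

  # heart rate: first-order recursive response to the demand fraction
  dt <- 1 / rate
  a <- dt / config$hr_tau
  # heart rate saturates at around 90% of peak aerobic power, so maximal
  # HR is approached during the final sustainable stages, not only at peak
  target <- p$hr_rest + (p$hr_max - p$hr_rest) *
    pmin(1, p_req / (0.9 * p$po_peak_per_kg * p$body_mass))
  hr <- as.numeric(stats::filter(a * target, 1 - a, method = "recursive",
                                 init = p$hr_rest))
  hr <- pmin(hr, p$hr_max)

  trace <- ergometer_trace(
    torque_left = m_side + noise(), torque_right = m_side + noise(),
    velocity_left = v, velocity_right = v,
    rate = rate, heart_rate = hr, test_start = 0)
  clip <- function(x) as.integer(min(10, max(1, round(x))))
  list(trace = trace,
       rpe_central = clip(stats::rnorm(1, 7, 1)),
       rpe_peripheral = clip(stats::rnorm(1, 9, 1)),
       exhausted = exhausted)
}

#' Simulate the full test battery for one participant
#'
#' Runs the protocol in its fixed sequence, scaling each test from the
#' previous test's extracted (not latent) outcome exactly as the pipeline
#' would in the laboratory: isometric trials -> F_iso -> P30 estimate ->
#' Wingate resistance -> Wingate -> measured P30 -> POpeak estimate -> GXT
#' schedule -> GXT.
#'
#' @param p a `participant_model`.
#' @param config a [sim_config()].
#' @return list with `participant`, `isometric` (list of traces), `sprint`
#'   (list of traces), `wingate` (trace), `gxt` (list as returned by
#'   [simulate_gxt()]), `prescription`, `schedule`.
#' @export
simulate_participant_tests <- function(p, config = sim_config()) {
  setup <- setup_for(p, config)
  iso <- lapply(seq_len(config$n_iso_trials), function(i)
    simulate_isometric(p, config))
  iso_fp <- lapply(iso, function(tr)
    compute_force_power(filter_trace(tr), setup))
  f_iso <- isometric_strength(iso_fp, p$body_mass)$f_iso

  sprints <- lapply(seq_len(config$n_sprints), function(i)
    simulate_sprint(p, config))

  est <- estimate_p30(f_iso, p$body_mass)
  presc <- wingate_resistance(est$p30_est, setup,
                              target_v = config$want_target_v)
  want <- simulate_wingate(p, presc, config)
  want_fp <- compute_force_power(filter_trace(want), setup)
  p30_meas <- wingate_outcomes(want_fp)$p30

  est2 <- estimate_popeak(p30_meas, p$body_mass)
  sched <- gxt_schedule(est2$po_peak_est, setup,
                        velocity = config$gxt_velocity)
  gxt <- simulate_gxt(p, sched, config)

  list(participant = p, isometric = iso, sprint = sprints, wingate = want,
       gxt = gxt, prescription = presc, schedule = sched)
}

#' Simulate the test battery for a whole cohort
#'
#' Deterministic under `config$seed` (a single RNG stream drives the
#' cohort draw and every trace in sequence).
#'
#' @param cohort list of `participant_model` objects.
#' @param config a [sim_config()].
#' @return list of per-participant test sets
#'   (see [simulate_participant_tests()]).
#' @export
simulate_cohort_tests <- function(cohort, config = sim_config()) {
  set.seed(config$seed + 1L)
  lapply(cohort, simulate_participant_tests, config = config)
}
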