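# Shared fixtures, built in code.

test_setup <- function(user_mass = 75) wheelchair_setup(user_mass = user_mass)

# Trace with identical constant channels on both sides.
const_trace <- function(torque = 10, velocity = 1, n = 500, rate = 100,
                        test_start = 0, heart_rate = NULL) {
  ergometer_trace(torque_left = rep(torque, n), torque_right = rep(torque, n),
                  velocity_left = rep(velocity, n),
                  velocity_right = rep(velocity, n),
                  rate = rate, test_start = test_start,
                  heart_rate = heart_rate)
}

# Force/power trace realizing a prescribed summed-power profile at a
# constant velocity, split equally over both sides (torque backed out of
# the power equation), without filtering.
fp_from_power <- function(power_total, velocity = 1, rate = 100,
                          setup = test_setup(), test_start = 0,
                          heart_rate = NULL) {
  m_side <- (power_total / 2) * setup$wheel_radius / velocity
  tr <- ergometer_trace(
    torque_left = m_side, torque_right = m_side,
    velocity_left = rep(velocity, length(power_total)),
    velocity_right = rep(velocity, length(power_total)),
    rate = rate, test_start = test_start, heart_rate = heart_rate)
  compute_force_power(tr, setup)
}

# Isometric-style force/power trace: constant per-side force, zero velocity.
fp_iso <- function(force_side, duration = 5, rate = 100,
                   setup = test_setup()) {
  n <- round(duration * rate)
  tr <- ergometer_trace(
    torque_left = rep(force_side * setup$rim_radius, n),
    torque_right = rep(force_side * setup$rim_radius, n),
    velocity_left = numeric(n), velocity_right = numeric(n),
    rate = rate, test_start = 0)
  compute_force_power(tr, setup)
}

# Independent brute-force oracle for the rolling-window kernel.
rolling_mean_max_oracle <- function(x, window, rate) {
  w <- as.integer(round(window * rate))
  means <- vapply(seq_len(length(x) - w + 1L),
                  function(i) mean(x[i:(i + w - 1L)]), numeric(1))
  i <- which.max(means)
  list(value = means[i], start_index = i)
}

# Independent brute-force oracle for the Theil-Sen estimator.
theil_sen_oracle <- function(x, y) {
  slopes <- c()
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (j > i && x[j] != x[i]) {
        slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
      }
    }
  }
  slope <- stats::median(slopes)
  list(slope = slope, intercept = stats::median(y - slope * x))
}
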