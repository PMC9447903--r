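test_that("trace construction enforces the time-base and channel contracts", {
  tr <- const_trace(n = 100)
  expect_s3_class(tr, "ergometer_trace")
  expect_equal(tr$time, (0:99) / 100)

  expect_error(ergometer_trace(1:5, 1:4, rep(1, 5), rep(1, 5)),
               class = "wheelcap_structure_error")
  expect_error(
    ergometer_trace(rep(1, 5), rep(1, 5), rep(1, 5), rep(1, 5),
                    time = c(0, 0.01, 0.02, 0.05, 0.06)),
    class = "wheelcap_timebase_error")
  expect_error(
    ergometer_trace(rep(1, 5), rep(1, 5), rep(-1, 5), rep(1, 5)),
    class = "wheelcap_structure_error")
  expect_error(const_trace(n = 100, test_start = 5),
               class = "wheelcap_structure_error")
})

test_that("low-pass filter has unit DC gain and rejects bad configurations", {
  tr <- const_trace(torque = 10, n = 500)
  f <- filter_trace(tr)
  expect_lt(max(abs(f$torque_left[100:400] - 10)), 1e-6)
  expect_equal(f$time, tr$time)
  expect_identical(f$test_start, tr$test_start)

  expect_error(filter_trace(const_trace(n = 10)),
               class = "wheelcap_short_signal_error")
  expect_error(filter_trace(const_trace(n = 500), cutoff = 60),
               class = "wheelcap_config_error")
})

test_that("filter attenuates above-cutoff content and passes the band", {
  t <- (0:9999) / 100
  x <- sin(2 * pi * 1 * t) + sin(2 * pi * 40 * t)
  tr <- ergometer_trace(torque_left = x + 2, torque_right = x + 2,
                        velocity_left = rep(1, 10000),
                        velocity_right = rep(1, 10000))
  f <- filter_trace(tr)
  # FFT amplitude oracle on the filtered synthetic signal
  amp <- function(y, freq) {
    n <- length(y)
    2 * abs(stats::fft(y - mean(y)))[freq * n / 100 + 1] / n
  }
  expect_lt(amp(f$torque_left, 40), 0.01)
  expect_equal(amp(f$torque_left, 1), 1, tolerance = 0.01)
})

test_that("zero-phase filtering does not shift a symmetric pulse peak", {
  n <- 600
  pulse <- c(rep(0, 250), seq(0, 1, length.out = 50),
             seq(1, 0, length.out = 50)[-1], rep(0, n - 349))
  tr <- ergometer_trace(torque_left = pulse, torque_right = pulse,
                        velocity_left = rep(1, n), velocity_right = rep(1, n))
  f <- filter_trace(tr)
  expect_lte(abs(which.max(f$torque_left) - which.max(pulse)), 1)
})

test_that("force and power follow the torque conversions exactly", {
  setup <- wheelchair_setup(user_mass = 75)  # r_r 0.31, r_w 0.34
  tr <- ergometer_trace(torque_left = rep(3.1, 50), torque_right = rep(3.1, 50),
                        velocity_left = rep(2, 50), velocity_right = rep(2, 50))
  fp <- compute_force_power(tr, setup)
  expect_equal(fp$force_left, rep(10, 50))        # 3.1 / 0.31
  expect_equal(fp$force_mean, rep(10, 50))

  tr2 <- ergometer_trace(torque_left = rep(3.4, 50), torque_right = rep(3.4, 50),
                         velocity_left = rep(2, 50), velocity_right = rep(2, 50))
  fp2 <- compute_force_power(tr2, setup)
  expect_equal(fp2$power_left, rep(20, 50))       # 3.4 / 0.34 * 2
  expect_equal(fp2$power_total, rep(40, 50))
  expect_equal(fp2$power_left, fp2$power_right)
})

test_that("per-sample power equals force * (r_r/r_w) * velocity on random traces", {
  set.seed(11)
  setup <- test_setup()
  m <- abs(rnorm(200, 5, 2))
  v <- abs(rnorm(200, 2, 0.5))
  tr <- ergometer_trace(torque_left = m, torque_right = m,
                        velocity_left = v, velocity_right = v)
  fp <- compute_force_power(tr, setup)
  ratio <- fp$power_total /
    (fp$force_mean * fp$velocity_mean * 2 * setup$rim_radius / setup$wheel_radius)
  expect_equal(ratio, rep(1, 200), tolerance = 1e-12)
})

test_that("rolling_mean_max matches hand-enumerated windows", {
  expect_equal(rolling_mean_max(rep(5, 30), 4, 1)$value, 5)

  r <- rolling_mean_max(c(0, 0, 10, 10, 0), 2, 1)
  expect_equal(r$value, 10)
  expect_equal(r$start_index, 3)

  # monotone ramp: maximising window anchors at the latest admissible start
  ramp <- 1:50
  r2 <- rolling_mean_max(ramp, 10, 1)
  expect_equal(r2$start_index, 41)
  expect_equal(r2$value, mean(41:50))

  expect_error(rolling_mean_max(1:5, 10, 1),
               class = "wheelcap_insufficient_data_error")
})

test_that("rolling_mean_max agrees with the brute-force oracle on random signals", {
  set.seed(21)
  for (k in 1:20) {
    n <- sample(20:400, 1)
    rate <- sample(c(1, 10, 100), 1)
    x <- rnorm(n)
    w <- sample(seq_len(max(1, n %/% rate)), 1)
    got <- rolling_mean_max(x, w, rate)
    want <- rolling_mean_max_oracle(x, w, rate)
    expect_equal(got$value, want$value)
    expect_equal(got$start_index, want$start_index)
  }
})

test_that("onset detection finds velocity and force onsets when no trigger is recorded", {
  setup <- test_setup()
  v <- c(rep(0, 100), rep(1.5, 200))
  tr <- ergometer_trace(torque_left = rep(1, 300), torque_right = rep(1, 300),
                        velocity_left = v, velocity_right = v)
  fp <- compute_force_power(tr, setup)
  expect_equal(detect_test_start(fp, "dynamic"), 1.00)

  f_side <- c(rep(0, 50), rep(100, 450))
  tr2 <- ergometer_trace(torque_left = f_side * setup$rim_radius,
                         torque_right = f_side * setup$rim_radius,
                         velocity_left = rep(0, 500), velocity_right = rep(0, 500))
  fp2 <- compute_force_power(tr2, setup)
  expect_equal(detect_test_start(fp2, "isometric"), 0.50)

  # recorded trigger wins over onset detection
  fp$test_start <- 0.25
  expect_equal(detect_test_start(fp, "dynamic"), 0.25)
})
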