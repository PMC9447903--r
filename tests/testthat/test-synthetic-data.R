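test_that("cohort generation is deterministic and honours the latent relations", {
  cfg <- sim_config(seed = 5)
  c1 <- generate_cohort(50, cfg)
  c2 <- generate_cohort(50, cfg)
  expect_identical(c1, c2)
  expect_false(identical(c1, generate_cohort(50, sim_config(seed = 6))))

  # zero-noise limit: latents satisfy the generating relations exactly
  cfg0 <- sim_config_noise_free(seed = 5)
  for (p in generate_cohort(30, cfg0)) {
    expect_equal(p$p30_per_kg, 0.51 * p$f_iso_per_kg - 0.18)
    expect_equal(p$po_peak_per_kg, 0.67 * p$p30_per_kg + 0.11)
  }

  masses <- vapply(generate_cohort(200, cfg), `[[`, numeric(1), "body_mass")
  expect_equal(mean(masses), 72, tolerance = 3 / 72)
  latents <- cohort_truth(generate_cohort(200, cfg))
  expect_true(all(latents$p30_per_kg > 0 & latents$po_peak_per_kg > 0))
})

test_that("simulated isometric trials recover the latent strength", {
  cfg <- sim_config_noise_free()
  p <- make_participant(body_mass = 80, f_iso_per_kg = 2.5)  # 200 N latent
  setup <- wheelchair_setup(user_mass = 80)
  tr <- simulate_isometric(p, cfg)
  r <- isometric_strength(compute_force_power(filter_trace(tr), setup), 80)
  expect_equal(r$f_iso, 200, tolerance = 0.01)

  # recovery error shrinks as the rise time constant goes to zero
  tr_fast <- simulate_isometric(p, sim_config_noise_free(iso_tau = 0.05))
  r_fast <- isometric_strength(compute_force_power(filter_trace(tr_fast), setup), 80)
  expect_lt(abs(r_fast$f_iso - 200), abs(r$f_iso - 200))

  expect_equal(max(tr$velocity_left), 0)
})

test_that("sprint dynamics obey the power balance and respond to resistance", {
  cfg <- sim_config_noise_free()
  p <- make_participant(body_mass = 75, f_iso_per_kg = 3.0)
  setup <- wheelchair_setup(user_mass = 75)

  tr <- simulate_sprint(p, cfg)
  fp <- compute_force_power(filter_trace(tr), setup)
  s <- sprint_outcomes(fp)
  expect_equal(s$po_mean, p$sprint_ratio * p$p30_per_kg * 75, tolerance = 0.005)

  # energy bookkeeping over the full sprint: work = KE gain + friction loss
  n <- length(tr$time)
  po_raw <- (tr$torque_left + tr$torque_right) / setup$wheel_radius * tr$velocity_left
  v <- tr$velocity_left
  work <- sum(po_raw) / tr$rate
  ke <- 0.5 * setup$total_mass * v[n]^2
  friction <- cfg$sprint_mu * setup$total_weight * sum(v) / tr$rate
  expect_equal(work, ke + friction, tolerance = 0.02)

  # doubling the resistance at a fixed force profile lowers the top speed
  tr_hi <- simulate_sprint(p, cfg, mu = 0.024)
  expect_lt(max(tr_hi$velocity_left), max(tr$velocity_left))
})

test_that("Wingate calibration hits the latent P30 and fatigue drives RF", {
  cfg <- sim_config_noise_free()
  p <- make_participant(body_mass = 75, f_iso_per_kg = 3.0)
  setup <- wheelchair_setup(user_mass = 75)
  presc <- wingate_resistance(estimate_p30(225, 75)$p30_est, setup)

  w <- wingate_outcomes(compute_force_power(filter_trace(
    simulate_wingate(p, presc, cfg)), setup))
  expect_equal(w$p30, p$p30_per_kg * 75, tolerance = 0.005)
  expect_gt(w$rf, 0)

  # without amplitude fade the only RF contribution is the spin-up from
  # standstill, which depresses the first interval (RF mildly negative);
  # the realized RF responds monotonically to the fade
  p0 <- make_participant(body_mass = 75, f_iso_per_kg = 3.0, fatigue_rate = 0)
  w0 <- wingate_outcomes(compute_force_power(filter_trace(
    simulate_wingate(p0, presc, cfg)), setup))
  expect_lt(w0$rf, 5)
  expect_gt(w0$rf, -40)
  expect_gt(w$rf - w0$rf, 20)

  # an over-performer against the same resistance approaches the 3 m/s limit
  p_hot <- make_participant(body_mass = 75, f_iso_per_kg = 3.0,
                            p30_per_kg = 1.5 * (0.51 * 3 - 0.18))
  w_hot <- wingate_outcomes(compute_force_power(filter_trace(
    simulate_wingate(p_hot, presc, cfg)), setup))
  expect_gt(w_hot$v_max, 2.9)
  expect_gt(w_hot$v_max, w$v_max)
})

test_that("GXT simulation fails at the first stage reaching capacity", {
  cfg <- sim_config_noise_free()
  setup <- wheelchair_setup(user_mass = 75)
  p <- make_participant(body_mass = 75, f_iso_per_kg = 3.0)
  popeak <- p$po_peak_per_kg * 75
  sched <- gxt_schedule(popeak, setup)

  g <- simulate_gxt(p, sched, cfg)
  expect_true(g$exhausted)
  go <- gxt_outcomes(compute_force_power(filter_trace(g$trace), setup),
                     g$rpe_central, g$rpe_peripheral)
  expect_equal(go$completed_stages, 10)
  expect_gte(go$duration, 600)
  expect_lte(go$duration, 660)

  # capacity at 70% of the estimate reproduces the under-8-min failure mode
  p_weak <- make_participant(body_mass = 75, f_iso_per_kg = 3.0,
                             po_peak_per_kg = 0.7 * p$po_peak_per_kg)
  g_weak <- simulate_gxt(p_weak, sched, cfg)
  go_weak <- gxt_outcomes(compute_force_power(filter_trace(g_weak$trace), setup), 7, 9)
  expect_lt(go_weak$duration, 480)

  # heart rate never exceeds the participant's maximum
  expect_lte(max(g$trace$heart_rate), p$hr_max)
  expect_equal(go$hr_peak, max(g$trace$heart_rate))

  # schedule exhausted before failure is flagged non-exhaustive
  g_short <- simulate_gxt(p, gxt_schedule(popeak, setup, n_stages = 3), cfg)
  expect_false(g_short$exhausted)
})

test_that("GXT stages satisfy the constant-velocity energy balance", {
  cfg <- sim_config_noise_free()
  setup <- wheelchair_setup(user_mass = 75)
  p <- make_participant(body_mass = 75, f_iso_per_kg = 3.0)
  sched <- gxt_schedule(p$po_peak_per_kg * 75, setup)
  g <- simulate_gxt(p, sched, cfg)
  fp <- compute_force_power(g$trace, setup)
  # interior of stage 3: mean PO = mu_3 * m_total * g * v
  idx <- which(fp$time >= 125 & fp$time < 175)
  expect_equal(mean(fp$power_total[idx]),
               sched$stage_mus[3] * setup$total_weight * 1.39,
               tolerance = 0.02)
})

test_that("traces are bit-identical under an identical seed and config", {
  cfg <- sim_config(seed = 12)
  t1 <- simulate_cohort_tests(generate_cohort(2, cfg), cfg)
  t2 <- simulate_cohort_tests(generate_cohort(2, cfg), cfg)
  expect_identical(t1, t2)
})
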