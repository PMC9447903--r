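test_that("percent deviation matches published rows and is exactly invertible", {
  expect_equal(round_half_up(percent_deviation(160, 125)), -22)
  expect_equal(round_half_up(percent_deviation(62, 82)), 32)
  expect_equal(percent_deviation(80, 80), 0)
  # antisymmetry: a d% inflation of the estimate reads back as exactly d
  for (d in c(-30, -5, 0, 12.5, 40)) {
    expect_equal(percent_deviation(100, 100 * (1 + d / 100)), d)
  }
  expect_error(percent_deviation(c(-1, 50), c(10, 40)),
               class = "wheelcap_config_error")
})

test_that("boundary flags count strict exceedances of the 20% band", {
  t1 <- load_table1()
  bw <- boundary_flags(t1$d_p30_pct, ids = t1$participant)
  expect_equal(bw$n_flagged, 3)
  expect_equal(bw$flagged_ids, c(4, 10, 19))

  bg <- boundary_flags(t1$d_popeak_pct, ids = t1$participant)
  expect_equal(bg$n_flagged, 6)
  expect_equal(bg$flagged_ids, c(2, 3, 17, 18, 19, 20))

  expect_equal(boundary_flags(rep(0, 10))$n_flagged, 0)
  expect_equal(boundary_flags(c(20, 20.1, -20, -20.1))$n_flagged, 2)
})

test_that("Theil-Sen matches hand-enumerated pairwise slopes", {
  fit <- theil_sen(c(1, 2, 3), c(1, 2, 4))
  expect_equal(fit$slope, 1.5)
  expect_equal(fit$intercept, -0.5)

  set.seed(61)
  x <- rnorm(30)
  fit2 <- theil_sen(x, 2 * x + 1)
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$intercept, 1)
  expect_equal(fit2$r_squared, 1)

  expect_error(theil_sen(c(1, 2), c(1, 2)),
               class = "wheelcap_insufficient_data_error")
  expect_error(theil_sen(rep(2, 5), 1:5),
               class = "wheelcap_degenerate_trace_error")
})

test_that("Theil-Sen agrees with the brute-force oracle on random instances", {
  set.seed(71)
  for (k in 1:15) {
    n <- sample(3:50, 1)
    x <- round(rnorm(n), 2)          # duplicated x values occur
    y <- 0.5 * x + rnorm(n, sd = 0.3)
    if (length(unique(x)) < 2) next
    got <- theil_sen(x, y)
    want <- theil_sen_oracle(x, y)
    expect_equal(got$slope, want$slope)
    expect_equal(got$intercept, want$intercept)
    expect_equal(got$n, n)
  }
})

test_that("Theil-Sen is order-invariant and more outlier-robust than least squares", {
  set.seed(81)
  x <- rnorm(19, 3, 0.8)
  y <- 0.5 * x - 0.1 + rnorm(19, sd = 0.1)
  fit <- theil_sen(x, y)
  perm <- sample(19)
  fit_p <- theil_sen(x[perm], y[perm])
  expect_equal(fit_p$slope, fit$slope)
  expect_equal(fit_p$intercept, fit$intercept)

  y_out <- y
  y_out[1] <- y[1] + 20
  ts_shift <- abs(theil_sen(x, y_out)$slope - fit$slope)
  ls_shift <- abs(coef(lm(y_out ~ x))[2] - coef(lm(y ~ x))[2])
  expect_lt(ts_shift, ls_shift)
})

test_that("reference-cohort regression reconstructs the strength-anaerobic slope", {
  t1 <- load_table1()
  fit <- theil_sen(t1$f_iso_N / t1$body_mass_kg,
                   t1$p30_meas_W / t1$body_mass_kg)
  expect_equal(fit$n, 19)
  expect_equal(fit$slope, 0.43, tolerance = 0.03 / 0.43)
  expect_lt(abs(fit$intercept), 0.05)
  expect_lt(fit$slope_p, 0.01)
  expect_gt(fit$intercept_p, 0.05)
  expect_equal(fit$r_squared, 0.82, tolerance = 0.05)

  fits <- cohort_regressions(t1)
  expect_equal(fits$n, c(19, 20, 20, 20, 20, 17))
  # aerobic-on-anaerobic association
  expect_equal(fits$slope[6], 0.46, tolerance = 0.1)
  expect_equal(fits$r_squared[6], 0.67, tolerance = 0.05)
})

test_that("estimate comparison selects the test by the normality screen", {
  t1 <- load_table1()
  cp30 <- compare_estimates(t1$p30_est_W, t1$p30_meas_W)
  expect_equal(cp30$n, 19)
  expect_identical(cp30$test_used, "wilcoxon")
  expect_false(cp30$significant)

  cpo <- compare_estimates(t1$popeak_est_W, t1$popeak_meas_W)
  expect_equal(cpo$n, 17)
  expect_identical(cpo$test_used, "paired t")
  expect_true(cpo$significant)
  expect_equal(cpo$mean_dev_pct, -10, tolerance = 0.02)
  expect_equal(cpo$sd_dev_pct, 16, tolerance = 0.05)

  # constructed constant bias with zero spread
  est <- c(100, 120, 80, 90, 110, 105)
  cb <- compare_estimates(est, est * 1.1)
  expect_equal(cb$mean_dev_pct, 10)
  expect_equal(cb$sd_dev_pct, 0)
})

test_that("cohort summary reproduces the published group means and ns", {
  t1 <- load_table1()
  s <- cohort_summary(t1)
  get <- function(v, f) s[s$variable == v, f]
  expect_equal(get("f_iso_N", "n"), 19)
  expect_equal(get("f_iso_N", "mean_rounded"), 214)
  expect_equal(get("p30_meas_W", "n"), 20)
  expect_equal(get("p30_meas_W", "mean_rounded"), 97)
  expect_equal(get("popeak_meas_W", "n"), 17)
  expect_equal(get("popeak_meas_W", "mean_rounded"), 61)
  expect_equal(get("sprint_v_max_ms", "mean_rounded"), 3.3)
  expect_equal(get("want_v_max_ms", "mean_rounded"), 2.4)
  expect_equal(get("body_mass_kg", "mean_rounded"), 72)
  expect_equal(get("body_mass_kg", "sd_rounded"), 11)

  one <- cohort_summary(t1[1, ])
  expect_equal(one[one$variable == "f_iso_N", "mean"], 129)
  expect_true(is.na(one[one$variable == "f_iso_N", "sd"]))
})

test_that("parameter recovery: generator latents regress back to the scaling slope", {
  cfg <- sim_config(seed = 97, sigma1 = 0.05)
  cohort <- generate_cohort(200, cfg)
  truth <- cohort_truth(cohort)
  fit <- theil_sen(truth$f_iso_per_kg, truth$p30_per_kg)
  expect_equal(fit$slope, 0.51, tolerance = 0.05 / 0.51)
})
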