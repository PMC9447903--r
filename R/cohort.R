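#' Percent deviation of a measured from an estimated outcome
#'
#' Delta = 100 * (measured - estimated) / estimated, the scatterplot
#' deviation used to judge how well each test's scaling predicted the next
#' test's outcome. Negative values mean the estimate was too high.
#'
#' @param est estimated values, W; must be positive where non-missing.
#' @param meas measured values, W.
#' @return percent deviations (vectorized; `NA` propagates).
#' @export
percent_deviation <- function(est, meas) {
  if (length(est) != length(meas)) {
    stop_wheelcap("est and meas must be paired", "wheelcap_structure_error")
  }
  if (any(est <= 0, na.rm = TRUE)) {
    stop_wheelcap("percent deviation undefined for non-positive estimates",
                  "wheelcap_config_error")
  }
  100 * (meas - est) / est
}

#' Flag deviations beyond a boundary
#'
#' Flags |Delta| strictly above the boundary (default 20%, the band derived
#' from the 10 +/- 2 min target duration of a graded test). Missing
#' deviations are never flagged.
#'
#' @param deviations percent deviations.
#' @param bound boundary, %.
#' @param ids optional identifiers parallel to `deviations`.
#' @return list with `flags` (logical, `NA`-free), `n_flagged`, `flagged_ids`.
#' @export
boundary_flags <- function(deviations, bound = 20, ids = seq_along(deviations)) {
  flags <- !is.na(deviations) & abs(deviations) > bound
  list(flags = flags, n_flagged = sum(flags), flagged_ids = ids[flags])
}

#' Theil-Sen robust regression
#'
#' Non-parametric line fit: the slope is the median of all pairwise slopes
#' (y_j - y_i)/(x_j - x_i) over pairs with distinct x, and the intercept is
#' the median of y - slope * x. Robust to outliers, which matters in small
#' heterogeneous cohorts. Explained variance is reported two ways, since
#' R^2 has no canonical definition for a non-least-squares line: the
#' squared Pearson correlation of x and y (`r_squared`, the headline
#' value) and 1 - SS_res/SS_tot around the fitted line
#' (`r_squared_line`). The slope p-value comes from Kendall's rank
#' correlation test and the intercept p-value from a Wilcoxon signed-rank
#' test of median residual = 0.
#'
#' @param x,y paired observations (per-kg outcomes in the protocol
#'   analyses); pairs with any `NA` are dropped.
#' @return a `theil_sen_fit`: `slope`, `intercept`, `r_squared`,
#'   `r_squared_line`, `n`, `slope_p`, `intercept_p`.
#' @export
theil_sen <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    stop_wheelcap("Theil-Sen regression needs at least 3 complete pairs",
                  "wheelcap_insufficient_data_error")
  }
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  ok <- dx != 0
  if (!any(ok)) {
    stop_wheelcap("all x identical: slope undefined", "wheelcap_degenerate_trace_error")
  }
  slope <- stats::median(dy[ok] / dx[ok])
  intercept <- stats::median(y - slope * x)
  res <- y - (intercept + slope * x)
  r2_line <- 1 - sum(res^2) / sum((y - mean(y))^2)
  slope_p <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall")$p.value)
  intercept_p <- suppressWarnings(
    stats::wilcox.test(res, mu = 0, exact = FALSE)$p.value)
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = stats::cor(x, y)^2, r_squared_line = r2_line,
         n = n, slope_p = slope_p, intercept_p = intercept_p),
    class = "theil_sen_fit")
}

#' @export
print.theil_sen_fit <- function(x, ...) {
  cat(sprintf("Theil-Sen fit: y = %.3f x %s %.3f  (R^2 = %.2f, n = %d)\n",
              x$slope, ifelse(x$intercept < 0, "-", "+"), abs(x$intercept),
              x$r_squared, x$n))
  cat(sprintf("  p(slope) = %.3g, p(intercept) = %.3g\n",
              x$slope_p, x$intercept_p))
  invisible(x)
}

#' Compare estimated with measured outcomes
#'
#' Paired comparison of the protocol's estimated against measured test
#' outcomes. Normality of the paired differences is screened with a
#' Shapiro-Wilk test; when the differences are non-normal (p < 0.05) the
#' headline p-value comes from a Wilcoxon signed-rank test, otherwise from
#' a paired t-test. Both test results are always reported; the gate only
#' selects which one headlines. Percent deviations are summarized as mean
#' and SD.
#'
#' @param est,meas paired outcome vectors, W; incomplete pairs dropped.
#' @param alpha significance level.
#' @return an `estimate_comparison`: `n`, `mean_dev_pct`, `sd_dev_pct`,
#'   `shapiro_p`, `wilcoxon_p`, `ttest_p`, `test_used`, `p_value`,
#'   `significant`.
#' @export
compare_estimates <- function(est, meas, alpha = 0.05) {
  if (length(est) != length(meas)) {
    stop_wheelcap("est and meas must be paired", "wheelcap_structure_error")
  }
  keep <- !(is.na(est) | is.na(meas))
  est <- est[keep]; meas <- meas[keep]
  if (length(est) < 5) {
    stop_wheelcap("need at least 5 complete pairs", "wheelcap_insufficient_data_error")
  }
  d <- meas - est
  dev <- percent_deviation(est, meas)
  shapiro_p <- if (stats::sd(d) == 0) 1 else stats::shapiro.test(d)$p.value
  wilcoxon_p <- suppressWarnings(
    stats::wilcox.test(meas, est, paired = TRUE, exact = FALSE)$p.value)
  ttest_p <- if (stats::sd(d) == 0) 1 else stats::t.test(meas, est, paired = TRUE)$p.value
  use_wilcoxon <- shapiro_p < alpha
  p <- if (use_wilcoxon) wilcoxon_p else ttest_p
  structure(
    list(n = length(est), mean_dev_pct = mean(dev), sd_dev_pct = stats::sd(dev),
         shapiro_p = shapiro_p, wilcoxon_p = wilcoxon_p, ttest_p = ttest_p,
         test_used = if (use_wilcoxon) "wilcoxon" else "paired t",
         p_value = p, significant = p < alpha),
    class = "estimate_comparison")
}

#' Cohort summary (mean/SD rows)
#'
#' Column-wise mean and SD over the available participants, with optional
#' display rounding (half-up) at per-column precision. `n` counts
#' non-missing values per column.
#'
#' @param table a cohort data frame (e.g. [load_table1()] or the output of
#'   [run_protocol()]).
#' @param digits named integer vector of display precisions; columns not
#'   named keep full precision. The default `table1_digits()` matches the
#'   bundled dataset's printed precision.
#' @return data frame with one row per numeric column: `variable`, `n`,
#'   `mean`, `sd`, `mean_rounded`, `sd_rounded`.
#' @export
cohort_summary <- function(table, digits = table1_digits()) {
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  num <- setdiff(num, "participant")
  rows <- lapply(num, function(v) {
    x <- table[[v]]
    n <- sum(!is.na(x))
    m <- mean(x, na.rm = TRUE)
    s <- if (n > 1) stats::sd(x, na.rm = TRUE) else NA_real_
    d <- if (v %in% names(digits)) digits[[v]] else NA_integer_
    data.frame(variable = v, n = n, mean = m, sd = s,
               mean_rounded = if (is.na(d)) m else round_half_up(m, d),
               sd_rounded = if (is.na(d) || is.na(s)) s else round_half_up(s, d))
  })
  do.call(rbind, rows)
}

#' Printed precision of the bundled cohort table's columns
#'
#' @return named integer vector of decimal places.
#' @export
table1_digits <- function() {
  c(age_yr = 0, body_mass_kg = 0, height_cm = 0, training_h_per_week = 0,
    f_iso_N = 0, f_iso_N_per_kg = 1,
    sprint_v_mean_ms = 1, sprint_v_max_ms = 1,
    sprint_po_mean_W = 0, sprint_po_mean_W_per_kg = 1,
    sprint_po_max_W = 0, sprint_po_max_W_per_kg = 1,
    p30_est_W = 0, p30_meas_W = 0, d_p30_pct = 0, p30_meas_W_per_kg = 1,
    p5_W = 0, want_po_max_W = 0, rf_pct = 0,
    want_v_mean_ms = 1, want_v_max_ms = 1,
    popeak_est_W = 0, popeak_meas_W = 0, d_popeak_pct = 0,
    popeak_meas_W_per_kg = 1,
    gxt_duration_s = 0, hr_peak_bpm = 0,
    rpe_central = 0, rpe_peripheral = 0, rpe_overall = 0)
}

#' Reconstruct the cohort's scaling regressions
#'
#' Fits the Theil-Sen regressions that underpin the protocol's scaling
#' equations on a cohort table: per-kg P30 on per-kg F_iso, on sprint
#' velocities and per-kg sprint powers, and per-kg POpeak on per-kg P30.
#' Per-kg regressors are computed from the absolute columns divided by body
#' mass (not from rounded per-kg columns).
#'
#' @param table a cohort data frame in the bundled dataset's schema.
#' @return data frame with one row per fitted association: dependent,
#'   independent, slope, intercept, r_squared, slope_p, intercept_p, n.
#' @export
cohort_regressions <- function(table) {
  m <- table$body_mass_kg
  specs <- list(
    list(dep = "P30 [W/kg]", ind = "F_iso [N/kg]",
         x = table$f_iso_N / m, y = table$p30_meas_W / m),
    list(dep = "P30 [W/kg]", ind = "sprint v_mean [m/s]",
         x = table$sprint_v_mean_ms, y = table$p30_meas_W / m),
    list(dep = "P30 [W/kg]", ind = "sprint v_max [m/s]",
         x = table$sprint_v_max_ms, y = table$p30_meas_W / m),
    list(dep = "P30 [W/kg]", ind = "sprint PO_mean [W/kg]",
         x = table$sprint_po_mean_W / m, y = table$p30_meas_W / m),
    list(dep = "P30 [W/kg]", ind = "sprint PO_max [W/kg]",
         x = table$sprint_po_max_W / m, y = table$p30_meas_W / m),
    list(dep = "POpeak [W/kg]", ind = "P30 [W/kg]",
         x = table$p30_meas_W / m, y = table$popeak_meas_W / m))
  do.call(rbind, lapply(specs, function(s) {
    fit <- theil_sen(s$x, s$y)
    data.frame(dependent = s$dep, independent = s$ind,
               slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, slope_p = fit$slope_p,
               intercept_p = fit$intercept_p, n = fit$n)
  }))
}
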