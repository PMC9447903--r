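#!/usr/bin/env Rscript
# Reference-cohort analysis: group summaries, estimated-vs-measured
# deviations, validity tallies and the Theil-Sen scaling regressions for
# the bundled 20-participant dataset. Writes results/ tables.

suppressPackageStartupMessages(library(wheelcap))
dir.create("results", showWarnings = FALSE)

t1 <- load_table1()

## Group summary (the Mean/SD rows) -----------------------------------------
summ <- cohort_summary(t1)
write.csv(summ, "results/cohort_summary.csv", row.names = FALSE)
get <- function(v) summ[summ$variable == v, ]
cat(sprintf("F_iso  %.0f +/- %.0f N (n=%d)\n", get("f_iso_N")$mean_rounded,
            get("f_iso_N")$sd_rounded, get("f_iso_N")$n))
cat(sprintf("P30    %.0f +/- %.0f W (n=%d)\n", get("p30_meas_W")$mean_rounded,
            get("p30_meas_W")$sd_rounded, get("p30_meas_W")$n))
cat(sprintf("POpeak %.0f +/- %.0f W (n=%d)\n\n", get("popeak_meas_W")$mean_rounded,
            get("popeak_meas_W")$sd_rounded, get("popeak_meas_W")$n))

## Estimated vs measured ------------------------------------------------------
cmp_p30 <- compare_estimates(t1$p30_est_W, t1$p30_meas_W)
cmp_pop <- compare_estimates(t1$popeak_est_W, t1$popeak_meas_W)
cat(sprintf("P30 est vs meas:    %s p = %.3f (dev %.0f +/- %.0f%%)\n",
            cmp_p30$test_used, cmp_p30$p_value, cmp_p30$mean_dev_pct,
            cmp_p30$sd_dev_pct))
cat(sprintf("POpeak est vs meas: %s p = %.3f (dev %.0f +/- %.0f%%)\n",
            cmp_pop$test_used, cmp_pop$p_value, cmp_pop$mean_dev_pct,
            cmp_pop$sd_dev_pct))

flags_want <- boundary_flags(t1$d_p30_pct, ids = t1$participant)
flags_gxt <- boundary_flags(t1$d_popeak_pct, ids = t1$participant)
cat(sprintf("Beyond the 20%% band: WAnT %d (participants %s), GXT %d (participants %s)\n\n",
            flags_want$n_flagged, paste(flags_want$flagged_ids, collapse = ","),
            flags_gxt$n_flagged, paste(flags_gxt$flagged_ids, collapse = ",")))

## Validity -------------------------------------------------------------------
g <- t1[!is.na(t1$gxt_duration_s), ]
reps <- lapply(seq_len(nrow(g)), function(i) {
  validate_gxt(list(duration = g$gxt_duration_s[i], hr_peak = g$hr_peak_bpm[i],
                    rpe_overall = g$rpe_overall[i]), age = g$age_yr[i])
})
want_valid <- vapply(seq_len(nrow(t1)), function(i) {
  validate_wingate(list(v_max = t1$want_v_max_ms[i],
                        v_mean = t1$want_v_mean_ms[i]))$valid
}, logical(1))
validity <- data.frame(
  criterion = c("WAnT v_max <= 3 m/s", "GXT duration 8-12 min",
                "GXT HR_peak >= 95% (200-age)", "GXT overall RPE >= 8"),
  n = c(nrow(t1), nrow(g), nrow(g), nrow(g)),
  failures = c(sum(!want_valid),
               sum(!vapply(reps, `[[`, logical(1), "gxt_duration_valid")),
               sum(!vapply(reps, `[[`, logical(1), "gxt_hr_valid")),
               sum(!vapply(reps, `[[`, logical(1), "gxt_rpe_valid"))))
write.csv(validity, "results/validity_counts.csv", row.names = FALSE)
print(validity, row.names = FALSE)
cat("\n")

## Theil-Sen scaling regressions ---------------------------------------------
fits <- cohort_regressions(t1)
write.csv(fits, "results/theil_sen_regressions.csv", row.names = FALSE)
print(cbind(fits[1:2],
            equation = sprintf("y = %.2f x %+.2f", fits$slope, fits$intercept),
            r_squared = round(fits$r_squared, 2), n = fits$n),
      row.names = FALSE)
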