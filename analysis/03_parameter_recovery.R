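#!/usr/bin/env Rscript
# Parameter recovery: with a 200-participant synthetic cohort at small
# latent noise (SD 0.05 W/kg), the full trace-level pipeline plus
# Theil-Sen regression should recover the generating scaling coefficients
# (0.51 for strength -> P30, 0.67 for P30 -> POpeak).

suppressPackageStartupMessages(library(wheelcap))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 211, sigma1 = 0.05, sigma2 = 0.05)
tab <- run_protocol(simulate_cohort_tests(generate_cohort(200, cfg), cfg), cfg)

m <- tab$body_mass_kg
f1 <- theil_sen(tab$f_iso_N / m, tab$p30_meas_W / m)
f2 <- theil_sen(tab$p30_meas_W / m, tab$popeak_meas_W / m)

out <- data.frame(
  relation = c("P30/kg on F_iso/kg", "POpeak/kg on P30/kg"),
  generating_slope = c(0.51, 0.67),
  recovered_slope = c(f1$slope, f2$slope),
  generating_intercept = c(-0.18, 0.11),
  recovered_intercept = c(f1$intercept, f2$intercept),
  r_squared = c(f1$r_squared, f2$r_squared),
  n = c(f1$n, f2$n))
write.csv(out, "results/parameter_recovery.csv", row.names = FALSE)
print(out, row.names = FALSE, digits = 3)

cat(sprintf("\nslope errors: %+.3f and %+.3f\n",
            f1$slope - 0.51, f2$slope - 0.67))
cat("note: the POpeak slope recovers slightly low because the minute-wise\n")
cat("stage quantization caps the measurable POpeak at the last completed\n")
cat("stage (up to 8% below true capacity) - the same mechanism that makes\n")
cat("real graded tests undershoot their estimate.\n")
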