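#!/usr/bin/env Rscript
# Assay validation on simulated molecular standards.
#
# Two questions a wet-lab user asks before trusting peak-height
# genotyping: (1) is the measured allelic fraction linear in the true
# mixing fraction across the 50:1 .. 1:50 standard grid, and (2) how much
# replicate scatter does template-sampling noise alone produce as input
# DNA is titrated down? Both are answered here purely from the binomial
# noise model.

library(asecall)

dir.create("results", showWarnings = FALSE)

## Standard curves at plasmid-scale input (30,000 copies/reaction)
series <- simulate_standard_series(copies = 30000, n_replicates = 4,
                                   seed = 101)
fit <- fit_standard_curve(series)
print(fit)
write.table(series, "results/standard_series.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## Replicate-SD sensitivity across template input (4 replicates, 1000 runs)
copies_grid <- c(300, 3000, 30000, 300000)
sens <- data.frame(
  copies = copies_grid,
  mean_sd_pct = vapply(seq_along(copies_grid), function(i) {
    sensitivity_sd(copies_grid[i], true_fraction = 0.5, n_replicates = 4,
                   n_runs = 1000, seed = 110 + i)
  }, numeric(1)),
  theoretical_sd_pct = 100 * sqrt(0.25 / copies_grid)
)
write.table(sens, "results/sensitivity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\nReplicate SD vs template input (p = 0.5, 4 replicates):\n")
print(sens, row.names = FALSE)
cat(sprintf(
  "\nFindings: the 13-point standard curve is linear with R^2 = %.4f;\n",
  fit$r_squared))
cat(sprintf(
  "replicate SD is %.2f points at 300,000 copies and %.2f points at 300\n",
  sens$mean_sd_pct[sens$copies == 300000],
  sens$mean_sd_pct[sens$copies == 300]))
cat("copies - binomial template sampling alone explains sub-2% scatter at\n")
cat("high input and keeps low-input scatter under 7 points.\n")
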