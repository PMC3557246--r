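#!/usr/bin/env Rscript
# Worked single-sample examples at cell-line scale.
#
# Three illustrative B-cell-line measurements (peak fractions as printed
# by the mass-spectrometry software) exercise the single-sample path:
# gDNA-corrected cDNA fractions, single-clone sequencing tallies, and the
# expected rebalancing of allelic expression under a demethylating agent.

library(asecall)

dir.create("results", showWarnings = FALSE)

examples <- data.frame(
  cell_line = c("imbalanced_line", "monoallelic_line", "balanced_line"),
  f_cdna = c(0.218, 0.0, 0.5),   # reference-allele share in cDNA
  f_gdna = c(0.49, 0.512, 0.5)   # matched gDNA share (heterozygous)
)
examples$f_corrected <- correct_by_gdna(examples$f_cdna, examples$f_gdna)
write.table(examples, "results/cell_line_ase.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("gDNA-corrected cDNA allelic fractions:\n")
print(examples, row.names = FALSE)

## Single-clone confirmation of the imbalanced line: 2 of 12 cDNA clones
## carried the under-expressed allele.
cf <- clone_fraction(2, 12)
cat(sprintf(
  "\nSingle-clone tally: %d/%d clones = %.0f%% (95%% CI %.1f-%.1f%%)\n",
  cf$n_ref, cf$n_total, 100 * cf$fraction, 100 * cf$ci_low,
  100 * cf$ci_high))

## Expected allelic rebalancing under a DNA-methyltransferase inhibitor,
## assuming expression proportional to the unmethylated fraction of each
## allele (allelic methylation 83% vs 32.3% as in the ASM analysis).
reb <- data.frame(efficiency = seq(0, 1, by = 0.25))
reb$fraction_ref <- vapply(reb$efficiency, function(e) {
  simulate_dac_rebalancing(0.83, 0.323, demethylation_efficiency = e)$fraction_after
}, numeric(1))
write.table(reb, "results/dac_rebalancing.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nDemethylation rebalancing (reference-allele fraction):\n")
print(reb, row.names = FALSE)

cat(sprintf(
  "\nFindings: the monoallelic line keeps %.0f%% of expression on one allele\nafter gDNA correction despite the biased gDNA read (48.8%% vs 51.2%%);\nfull demethylation moves the imbalanced line from %.3f to 0.500, while\nzero efficiency (mock/withdrawal) leaves the imbalance untouched.\n",
  100 * (1 - examples$f_corrected[2]),
  simulate_dac_rebalancing(0.83, 0.323, 0)$fraction_before))
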