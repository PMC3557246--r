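#!/usr/bin/env Rscript
# Allele-specific methylation (ASM) analysis on synthetic bisulfite data.
#
# A promoter region showing ~50% aggregate methylation can hide two very
# different allele populations. Here 20 clones per allele are simulated
# with per-CpG methylation probabilities 0.83 (allele A) and 0.323
# (allele B), split by the phasing SNP, and summarized over the +58..+263
# window; the ASM-SNuPE genotyping of methylation-specific amplicons and
# the standards-based normalization of per-CpG calls are exercised
# alongside.

library(asecall)

dir.create("results", showWarnings = FALSE)

## Bisulfite clone matrix, split by the phasing SNP
clones <- simulate_bisulfite_clones(
  n_clones_per_allele = 20, p_meth_a = 0.83, p_meth_b = 0.323,
  n_cpgs = 10, missing_rate = 0.05, seed = 131)
write_clones(clones, "results/clones.tsv")
print(clones)
sp <- split_clones_by_allele(clones)
win <- c(58, 263)
lev <- c(A = region_methylation(sp$A, win[1], win[2]),
         B = region_methylation(sp$B, win[1], win[2]),
         pooled = region_methylation(clones, win[1], win[2]))
cat(sprintf(
  "\nRegion methylation (+%d..+%d): allele A %.1f%%, allele B %.1f%%, pooled %.1f%%\n",
  win[1], win[2], lev["A"], lev["B"], lev["pooled"]))

## ASM-SNuPE: genotype split between methylation-specific amplicons
asm <- asm_snupe(
  meth_pair = list(intensity_ref = 4, intensity_alt = 96),
  unmeth_pair = list(intensity_ref = 93, intensity_alt = 7),
  control_m_frac = c(meth = 0.97, unmeth = 0.03))
print(asm)

## Per-CpG normalization against 0/20/40/60/80/100% mixing standards
## (simulated with a 0.85 gain and +4 offset detector distortion)
standards <- data.frame(nominal_pct = seq(0, 100, 20))
standards$measured_pct <- 0.85 * standards$nominal_pct + 4
profile <- data.frame(
  amplicon_id = "D",
  position = clones$positions,
  raw_pct = 0.85 * c(lev["A"], lev["B"])[
    1 + (seq_along(clones$positions) %% 2)] + 4)
normalized <- normalize_methylation(profile, standards)
write.table(normalized, "results/methylation_normalized.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## Group comparison: intron-1 methylation, 7 most imbalanced vs 7 most
## balanced samples (synthetic; planted +25-point shift)
imbalanced <- withr::with_seed(141, rnorm(7, 42, 8))
balanced <- withr::with_seed(142, rnorm(7, 17, 8))
cmp <- compare_group_methylation(imbalanced, balanced)
cat(sprintf(
  "\nImbalanced vs balanced intron-1 methylation: medians %.1f%% vs %.1f%%, Mann-Whitney p = %.4g\n",
  cmp$median1, cmp$median2, cmp$p))

cat("\nFindings: the allele split uncovers an ~83%/~32% methylation\n")
cat("asymmetry behind an ~58% pooled signal; the ASM-SNuPE control CpG\n")
cat("validates amplicon purity and the genotype split calls ASM; linear\n")
cat("normalization recovers the undistorted per-CpG percentages; and the\n")
cat("planted intron-1 shift is detected at p < 0.01.\n")
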