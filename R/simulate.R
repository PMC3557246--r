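# Synthetic-data generators. These emulate the statistical structure the
# assay analytics assume: binomial template-sampling noise at a given
# template copy number, deterministic per-allele detection gain (the bias
# the gDNA correction must cancel), a control cohort tightly distributed
# around allelic balance with bi-directionally planted ASE among cases,
# allele-specific bisulfite clone populations, and demethylation-driven
# rebalancing of allelic expression.
#
# Every generator takes one explicit seed and leaves the global RNG state
# untouched (withr::with_seed); fixed seed implies bit-identical output.

#' Default 13-point standard-series mixing ratios (50:1 down to 1:50)
#' @export
standard_ratios <- function() {
  c(50, 25, 10, 7, 5, 2, 1, 1 / 2, 1 / 5, 1 / 7, 1 / 10, 1 / 25, 1 / 50)
}

#' Simulate replicate peak-pair measurements of one sample
#'
#' Per replicate, the number of reference-allele template molecules is
#' drawn as Binomial(`copies`, `true_fraction`); peak intensities are the
#' allele counts scaled by the per-allele detection gains. With unequal
#' gains the measured fraction converges to
#' \eqn{g_r p / (g_r p + g_a (1-p))}, the multiplicative bias that
#' [correct_by_gdna()] removes.
#'
#' @param true_fraction True reference-allele fraction in \[0, 1\].
#' @param copies Template molecules per reaction (>= 1).
#' @param n_replicates Number of technical replicates; default 4.
#' @param gain_ref,gain_alt Per-allele detection gains (> 0); default 1.
#' @param seed Integer seed.
#' @param sample_id,snp_id,analyte,allele_ref,allele_alt Identifiers for
#'   the emitted records.
#' @return Peak data frame (one row per replicate) with the `peaks.tsv`
#'   schema: `sample_id`, `snp_id`, `analyte`, `replicate`, `allele_ref`,
#'   `allele_alt`, `intensity_ref`, `intensity_alt`.
#' @export
simulate_measurement <- function(true_fraction, copies, n_replicates = 4L,
                                 gain_ref = 1, gain_alt = 1, seed = 1L,
                                 sample_id = "S1", snp_id = "rs1056719",
                                 analyte = "cdna",
                                 allele_ref = "G", allele_alt = "A") {
  stopifnot(true_fraction >= 0, true_fraction <= 1, copies >= 1,
            n_replicates >= 1L, gain_ref > 0, gain_alt > 0)
  copies <- round(copies)
  counts <- withr::with_seed(seed,
    stats::rbinom(n_replicates, size = copies, prob = true_fraction))
  data.frame(
    sample_id = sample_id, snp_id = snp_id, analyte = analyte,
    replicate = seq_len(n_replicates),
    allele_ref = allele_ref, allele_alt = allele_alt,
    intensity_ref = gain_ref * counts,
    intensity_alt = gain_alt * (copies - counts),
    stringsAsFactors = FALSE
  )
}

#' Simulate a plasmid/gDNA standard series
#'
#' Standards mixed at molar ratios r (reference : alternate copies) have
#' expected reference-allele fraction r/(1+r); measured fractions are
#' generated with binomial template sampling at `copies` total molecules
#' per reaction.
#'
#' @param ratios Positive mixing ratios; default [standard_ratios()].
#' @param copies Template molecules per reaction; default 30000.
#' @param n_replicates Replicates per ratio; default 4.
#' @param gain_ref,gain_alt Per-allele detection gains; default 1.
#' @param seed Integer seed.
#' @param snp_id Assay identifier.
#' @return Data frame with one row per (ratio, replicate):
#'   `snp_id`, `nominal_ratio`, `expected_fraction`, `copies_total`,
#'   `replicate`, `intensity_ref`, `intensity_alt`, `measured_fraction`.
#' @export
simulate_standard_series <- function(ratios = standard_ratios(),
                                     copies = 30000, n_replicates = 4L,
                                     gain_ref = 1, gain_alt = 1,
                                     seed = 1L, snp_id = "rs1056719") {
  stopifnot(all(ratios > 0))
  out <- do.call(rbind, lapply(seq_along(ratios), function(i) {
    r <- ratios[i]
    ef <- r / (1 + r)
    m <- simulate_measurement(ef, copies, n_replicates,
                              gain_ref = gain_ref, gain_alt = gain_alt,
                              seed = seed + i - 1L,
                              sample_id = sprintf("std_%02d", i),
                              snp_id = snp_id, analyte = "gdna")
    data.frame(
      snp_id = snp_id, nominal_ratio = r, expected_fraction = ef,
      copies_total = round(copies), replicate = m$replicate,
      intensity_ref = m$intensity_ref, intensity_alt = m$intensity_alt,
      measured_fraction = allelic_fraction(m$intensity_ref, m$intensity_alt),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  # rejection sampling; truncation bounds here are >2 sd from the mean at
  # worst, so acceptance stays high
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Simulate a case/control cohort of corrected allelic fractions
#'
#' Controls and balanced cases are drawn from truncated normal
#' distributions around allelic balance; planted ASE cases are drawn
#' uniformly from extreme ranges on either side (ASE is bi-directional).
#'
#' @param n_controls,n_balanced Group sizes.
#' @param control_mean,control_sd,control_range Control distribution
#'   (truncated normal; `control_range` is the length-2 truncation
#'   interval).
#' @param balanced_mean,balanced_sd,balanced_range Balanced-case
#'   distribution.
#' @param planted List of `list(n =, low =, high =)` blocks; each plants
#'   `n` ASE-positive cases uniform on `[low, high]`. Ranges must be
#'   disjoint from the balanced-case truncation range.
#' @param seed Integer seed.
#' @return Cohort data frame (`sample_id`, `group`, `fraction`) with a
#'   logical attribute `"planted"` marking the planted ASE cases.
#' @export
simulate_cohort <- function(n_controls, n_balanced,
                            control_mean = 0.43, control_sd = 0.03,
                            control_range = c(0.33, 0.53),
                            balanced_mean = 0.40, balanced_sd = 0.04,
                            balanced_range = c(0.31, 0.52),
                            planted = list(), seed = 1L) {
  stopifnot(n_controls >= 0L, n_balanced >= 0L,
            length(control_range) == 2L, length(balanced_range) == 2L)
  for (p in planted) {
    stopifnot(all(c("n", "low", "high") %in% names(p)),
              p$low < p$high, p$low >= 0, p$high <= 1)
    if (p$high >= balanced_range[1L] && p$low <= balanced_range[2L]) {
      stop("planted range [", p$low, ", ", p$high,
           "] overlaps the balanced-case core [",
           balanced_range[1L], ", ", balanced_range[2L], "]")
    }
  }
  withr::with_seed(seed, {
    controls <- rtruncnorm(n_controls, control_mean, control_sd,
                           control_range[1L], control_range[2L])
    balanced <- rtruncnorm(n_balanced, balanced_mean, balanced_sd,
                           balanced_range[1L], balanced_range[2L])
    extremes <- unlist(lapply(planted, function(p) {
      stats::runif(p$n, p$low, p$high)
    }))
  })
  if (is.null(extremes)) extremes <- numeric(0)
  n_cases <- n_balanced + length(extremes)
  cohort <- data.frame(
    sample_id = c(sprintf("ctrl_%03d", seq_len(n_controls)),
                  sprintf("case_%03d", seq_len(n_cases))),
    group = c(rep("control", n_controls), rep("case", n_cases)),
    fraction = c(controls, balanced, extremes),
    stringsAsFactors = FALSE
  )
  attr(cohort, "planted") <- c(rep(FALSE, n_controls + n_balanced),
                               rep(TRUE, length(extremes)))
  cohort
}

#' Reference synthetic cohorts (fixtures A and B)
#'
#' Two frozen cohort designs used throughout the tests and the analysis
#' scripts. Fixture A (seed 42) mimics the published cohort layout: 63
#' controls ~ N(0.43, 0.03^2) truncated to \[0.33, 0.53\], 103 balanced
#' cases ~ N(0.40, 0.04^2) truncated to \[0.31, 0.52\], and 17 planted
#' bi-directional ASE cases (9 uniform on \[0.08, 0.22\], 8 on
#' \[0.60, 0.80\]). Fixture B (seed 43) carries 110 balanced cases
#' truncated to \[0.32, 0.50\] plus 10 extreme planted cases (5 on
#' \[0.05, 0.15\], 5 on \[0.70, 0.85\]) and no controls (it feeds the
#' alpha-outlier caller, which uses cases only).
#'
#' @param fixture `"A"` or `"B"`.
#' @param seed Override the fixture's frozen seed (42 for A, 43 for B).
#' @return Cohort data frame as in [simulate_cohort()].
#' @export
cohort_fixture <- function(fixture = c("A", "B"), seed = NULL) {
  fixture <- match.arg(fixture)
  if (fixture == "A") {
    simulate_cohort(
      n_controls = 63L, n_balanced = 103L,
      control_mean = 0.43, control_sd = 0.03, control_range = c(0.33, 0.53),
      balanced_mean = 0.40, balanced_sd = 0.04, balanced_range = c(0.31, 0.52),
      planted = list(list(n = 9L, low = 0.08, high = 0.22),
                     list(n = 8L, low = 0.60, high = 0.80)),
      seed = if (is.null(seed)) 42L else seed)
  } else {
    simulate_cohort(
      n_controls = 0L, n_balanced = 110L,
      balanced_mean = 0.40, balanced_sd = 0.04, balanced_range = c(0.32, 0.50),
      planted = list(list(n = 5L, low = 0.05, high = 0.15),
                     list(n = 5L, low = 0.70, high = 0.85)),
      seed = if (is.null(seed)) 43L else seed)
  }
}

#' Simulate a bisulfite clone matrix with allele-specific methylation
#'
#' Each allele's clones call `"M"` at every CpG independently with that
#' allele's methylation probability; calls go missing independently at
#' `missing_rate`.
#'
#' @param n_clones_per_allele Clones per allele group.
#' @param p_meth_a,p_meth_b Per-CpG methylation probability on allele A
#'   and B.
#' @param n_cpgs Number of CpG positions.
#' @param missing_rate Probability a call is missing; default 0.
#' @param positions Integer TSS offsets for the CpGs; default an evenly
#'   spaced grid on +58..+263 (the allele-resolved window used in the
#'   analysis scripts).
#' @param seed Integer seed.
#' @return A `"clone_matrix"` with `n_clones_per_allele` clones labelled
#'   `"A"` followed by the same number labelled `"B"`.
#' @export
simulate_bisulfite_clones <- function(n_clones_per_allele, p_meth_a,
                                      p_meth_b, n_cpgs,
                                      missing_rate = 0, positions = NULL,
                                      seed = 1L) {
  stopifnot(n_clones_per_allele >= 1L, n_cpgs >= 1L,
            p_meth_a >= 0, p_meth_a <= 1, p_meth_b >= 0, p_meth_b <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (is.null(positions)) {
    positions <- round(seq(58, 263, length.out = n_cpgs))
  }
  stopifnot(length(positions) == n_cpgs)
  n <- 2L * n_clones_per_allele
  calls <- withr::with_seed(seed, {
    p <- rep(c(p_meth_a, p_meth_b), each = n_clones_per_allele)
    m <- matrix(ifelse(stats::runif(n * n_cpgs) <
                         rep(p, times = n_cpgs), "M", "U"),
                nrow = n, ncol = n_cpgs)
    m[matrix(stats::runif(n * n_cpgs) < missing_rate,
             nrow = n, ncol = n_cpgs)] <- NA_character_
    m
  })
  colnames(calls) <- positions
  bisulfite_clone_matrix(calls,
                         rep(c("A", "B"), each = n_clones_per_allele))
}

#' Expected allelic-expression rebalancing under demethylation
#'
#' Deterministic model of a demethylating-agent (e.g. DAC) experiment:
#' each allele's expression is proportional to
#' `baseline_expression * (1 - methylation)`; treatment multiplies each
#' allele's methylation by `1 - demethylation_efficiency`. Full
#' demethylation therefore restores allelic balance (fraction 0.5), zero
#' efficiency (mock treatment or recovery after withdrawal) leaves the
#' imbalance unchanged.
#'
#' @param methylation_a,methylation_b Allelic methylation levels in
#'   \[0, 1\] (allele A is the reference allele).
#' @param demethylation_efficiency Fraction of methylation erased, in
#'   \[0, 1\].
#' @param baseline_expression Common expression scale (> 0); cancels from
#'   the fractions.
#' @return List with `fraction_before` and `fraction_after`
#'   (reference-allele expression fractions).
#' @export
simulate_dac_rebalancing <- function(methylation_a, methylation_b,
                                     demethylation_efficiency,
                                     baseline_expression = 1) {
  stopifnot(methylation_a >= 0, methylation_a <= 1,
            methylation_b >= 0, methylation_b <= 1,
            demethylation_efficiency >= 0, demethylation_efficiency <= 1,
            baseline_expression > 0)
  frac <- function(ma, mb) {
    ea <- baseline_expression * (1 - ma)
    eb <- baseline_expression * (1 - mb)
    if (ea + eb == 0) stop("no expression: both alleles fully silenced")
    ea / (ea + eb)
  }
  list(
    fraction_before = frac(methylation_a, methylation_b),
    fraction_after = frac(methylation_a * (1 - demethylation_efficiency),
                          methylation_b * (1 - demethylation_efficiency))
  )
}
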