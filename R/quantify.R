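# Peak-pair quantification: raw two-allele MALDI-TOF peak intensities ->
# calibrated, gDNA-corrected allelic fractions.

#' Reference-allele fraction from a peak-intensity pair
#'
#' In a SNuPE/MALDI-TOF assay each allele of a heterozygous SNP produces a
#' distinct mass peak; the relative abundance of the reference allele is
#' estimated by its share of the summed peak heights,
#' \eqn{f = h_{ref} / (h_{ref} + h_{alt})}.
#'
#' @param intensity_ref,intensity_alt Non-negative peak heights (arbitrary
#'   signal units) for the reference and alternate allele. Vectorized.
#' @param sample_id,snp_id,replicate Optional identifiers used only to make
#'   the empty-spectrum error message traceable.
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' allelic_fraction(51, 49)  # 0.51
#' allelic_fraction(100, 0)  # monoallelic, 1
#' @export
allelic_fraction <- function(intensity_ref, intensity_alt,
                             sample_id = NULL, snp_id = NULL,
                             replicate = NULL) {
  stopifnot(is.numeric(intensity_ref), is.numeric(intensity_alt),
            length(intensity_ref) == length(intensity_alt))
  if (any(intensity_ref < 0, na.rm = TRUE) ||
      any(intensity_alt < 0, na.rm = TRUE)) {
    stop("peak intensities must be non-negative")
  }
  total <- intensity_ref + intensity_alt
  bad <- which(total == 0)
  if (length(bad) > 0L) {
    i <- bad[1L]
    ctx <- paste(c(
      if (!is.null(sample_id)) paste0("sample ", sample_id[pmin(i, length(sample_id))]),
      if (!is.null(snp_id)) paste0("SNP ", snp_id[pmin(i, length(snp_id))]),
      if (!is.null(replicate)) paste0("replicate ", replicate[pmin(i, length(replicate))])
    ), collapse = ", ")
    stop("empty spectrum (both allele intensities zero)",
         if (nzchar(ctx)) paste0(": ", ctx) else "")
  }
  intensity_ref / total
}

#' Aggregate technical replicates into per-sample allelic fractions
#'
#' Reactions are run in technical replicates (typically 4-6). Replicates
#' whose total peak intensity falls below `min_total_intensity` are dropped
#' as failed reactions; the remaining per-replicate fractions are averaged
#' and their sample standard deviation is reported in percentage points.
#'
#' @param peaks Data frame of peak-pair measurements with columns
#'   `sample_id`, `snp_id`, `analyte`, `replicate`, `intensity_ref`,
#'   `intensity_alt` (see [read_peaks()]).
#' @param min_total_intensity QC threshold on `intensity_ref +
#'   intensity_alt` per replicate; default 0 (filter off).
#' @return Data frame with one row per (sample_id, snp_id, analyte):
#'   `fraction` (mean reference-allele fraction), `sd_pct` (sample SD across
#'   passing replicates, percentage points; 0 for a single replicate) and
#'   `n_replicates` (passing count).
#' @export
aggregate_replicates <- function(peaks, min_total_intensity = 0) {
  peaks <- validate_peaks(peaks)
  total <- peaks$intensity_ref + peaks$intensity_alt
  keep <- total >= min_total_intensity & total > 0
  key <- interaction(peaks$sample_id, peaks$snp_id, peaks$analyte,
                     drop = TRUE, sep = "\r")
  if (any(tapply(keep, key, sum) == 0L)) {
    failed <- names(which(tapply(keep, key, sum) == 0L))[1L]
    stop("QC failure: no replicate passed the intensity threshold for ",
         gsub("\r", " / ", failed, fixed = TRUE))
  }
  peaks <- peaks[keep, , drop = FALSE]
  key <- key[keep]
  frac <- allelic_fraction(peaks$intensity_ref, peaks$intensity_alt,
                           peaks$sample_id, peaks$snp_id, peaks$replicate)
  first <- which(!duplicated(key))
  idx <- as.character(key[first])
  means <- tapply(frac, key, mean)
  sds <- tapply(frac, key, function(v) if (length(v) > 1L) stats::sd(v) else 0)
  ns <- tapply(frac, key, length)
  out <- data.frame(
    sample_id = peaks$sample_id[first],
    snp_id = peaks$snp_id[first],
    analyte = peaks$analyte[first],
    fraction = as.numeric(means[idx]),
    sd_pct = 100 * as.numeric(sds[idx]),
    n_replicates = as.integer(ns[idx]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Correct a cDNA allelic fraction by the matched gDNA fraction
#'
#' In a heterozygous sample the two alleles are present 1:1 in genomic DNA,
#' so any departure of the measured gDNA fraction from 0.5 reflects
#' assay-intrinsic allelic detection bias (unequal per-allele gains).
#' Odds normalization divides the cDNA allelic odds by the gDNA allelic
#' odds and maps back to a fraction:
#' \deqn{f_{corr} = \frac{f_c/f_g}{f_c/f_g + (1-f_c)/(1-f_g)}}
#' This cancels a multiplicative per-allele gain exactly, returns 0.5
#' whenever the cDNA and gDNA fractions agree, and preserves the
#' monoallelic endpoints 0 and 1.
#'
#' @param f_cdna Measured cDNA reference-allele fraction in \[0, 1\].
#' @param f_gdna Measured gDNA reference-allele fraction, strictly inside
#'   (0, 1) (a homozygous sample carries no allelic information).
#' @param het_band Length-2 numeric; gDNA fractions outside this band are
#'   treated as dubious heterozygotes and trigger a warning (the correction
#'   is still returned). Default `c(0.3, 0.7)`.
#' @return Corrected fraction(s) in \[0, 1\].
#' @examples
#' correct_by_gdna(0.6, 0.6)       # identical bias cancels -> 0.5
#' correct_by_gdna(1.0, 0.488)     # monoallelic stays monoallelic -> 1
#' @export
correct_by_gdna <- function(f_cdna, f_gdna, het_band = c(0.3, 0.7)) {
  stopifnot(is.numeric(f_cdna), is.numeric(f_gdna),
            length(het_band) == 2L, het_band[1] < het_band[2])
  if (any(f_cdna < 0 | f_cdna > 1, na.rm = TRUE)) {
    stop("f_cdna must lie in [0, 1]")
  }
  if (any(f_gdna <= 0 | f_gdna >= 1, na.rm = TRUE)) {
    stop("non-informative genotype: gDNA fraction of 0 or 1 implies a ",
         "homozygous sample; gDNA correction requires heterozygosity")
  }
  out_band <- f_gdna < het_band[1] | f_gdna > het_band[2]
  if (any(out_band, na.rm = TRUE)) {
    warning(sum(out_band, na.rm = TRUE), " gDNA fraction(s) outside the ",
            "heterozygosity band [", het_band[1], ", ", het_band[2],
            "]; sample(s) of doubtful informativity")
  }
  odds <- (f_cdna / f_gdna)
  odds_alt <- (1 - f_cdna) / (1 - f_gdna)
  odds / (odds + odds_alt)
}

#' Fit a standard curve for assay calibration
#'
#' Plasmid (or genomic-DNA) standards mixed at known molar ratios define
#' expected reference-allele fractions \eqn{r/(1+r)}; the measured fractions
#' are regressed on the expected ones by ordinary least squares and the
#' squared Pearson correlation is reported.
#'
#' @param standards Data frame with numeric columns `expected_fraction` and
#'   `measured_fraction` (one row per measurement; replicate rows allowed).
#' @return Object of class `"calibration_result"`: list with `slope`,
#'   `intercept`, `r_squared`, `n_points`.
#' @export
fit_standard_curve <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("expected_fraction", "measured_fraction") %in% names(standards)))
  x <- standards$expected_fraction
  y <- standards$measured_fraction
  if (length(unique(x)) < 3L) {
    stop("standard curve needs at least 3 distinct nominal ratios")
  }
  if (stats::var(x) == 0) stop("zero variance in expected fractions")
  if (any(y < 0 | y > 1)) stop("measured fractions must lie in [0, 1]")
  fit <- stats::lm(y ~ x)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = stats::cor(x, y)^2,
         n_points = length(x)),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Standard-curve calibration (%d points)\n  measured = %.4f * expected + %.4f,  R^2 = %.4f\n",
    x$n_points, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Replicate-SD sensitivity of the assay at a given template input
#'
#' Simulates repeated experiments of `n_replicates` binomial peak-pair
#' measurements at `copies` template molecules and returns the mean
#' across experiments of the per-experiment replicate standard deviation,
#' in percentage points. Measures how measurement dispersion grows as
#' template input shrinks (template-sampling noise scales as
#' \eqn{\sqrt{p(1-p)/copies}}).
#'
#' @param copies Template molecules per reaction (>= 1).
#' @param true_fraction True reference-allele fraction; default 0.5.
#' @param n_replicates Replicates per experiment (>= 2); default 4.
#' @param n_runs Number of simulated experiments; default 1000.
#' @param seed Integer seed (applied locally, global RNG state untouched).
#' @return Mean replicate SD in percentage points.
#' @export
sensitivity_sd <- function(copies, true_fraction = 0.5, n_replicates = 4L,
                           n_runs = 1000L, seed = 1L) {
  stopifnot(copies >= 1, n_replicates >= 2L, n_runs >= 1L,
            true_fraction >= 0, true_fraction <= 1)
  withr::with_seed(seed, {
    sds <- vapply(seq_len(n_runs), function(i) {
      f <- stats::rbinom(n_replicates, size = round(copies),
                         prob = true_fraction) / round(copies)
      stats::sd(f)
    }, numeric(1))
    100 * mean(sds)
  })
}

#' Allele fraction from single-clone sequencing counts
#'
#' Single cloned RT-PCR products are Sanger-sequenced and each clone is
#' assigned to one allele; the reference-allele fraction and its exact
#' Clopper-Pearson 95% confidence interval summarize the tally.
#'
#' @param n_ref Clones carrying the reference allele.
#' @param n_total Total clones sequenced (>= 1).
#' @param conf_level Confidence level, default 0.95.
#' @return List with `fraction`, `ci_low`, `ci_high`, `n_ref`, `n_total`.
#' @examples
#' clone_fraction(2, 12)  # 2 of 12 clones -> 17%
#' @export
clone_fraction <- function(n_ref, n_total, conf_level = 0.95) {
  stopifnot(length(n_ref) == 1L, length(n_total) == 1L)
  if (n_total < 1L) stop("at least one clone is required")
  if (n_ref < 0L || n_ref > n_total) stop("n_ref must lie in [0, n_total]")
  bt <- stats::binom.test(n_ref, n_total, conf.level = conf_level)
  list(fraction = n_ref / n_total,
       ci_low = unname(bt$conf.int[1L]),
       ci_high = unname(bt$conf.int[2L]),
       n_ref = as.integer(n_ref), n_total = as.integer(n_total))
}
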