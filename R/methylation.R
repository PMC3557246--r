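# Promoter methylation quantification and allele-specific methylation
# (ASM): standards-based normalization of mass-spectrometric methylation
# calls, bisulfite clone matrices split by a phasing SNP, and the
# methylation-specific SNuPE genotyping with its specificity control.
#
# Coordinates throughout are integer offsets relative to the transcription
# start site (TSS = +1, no position 0); windows are closed intervals.

#' Normalize per-CpG methylation against mixing standards
#'
#' Mass-spectrometric methylation calls are calibrated against standards of
#' known methylation (0-100% mixes of fully methylated and unmethylated
#' whole-genome-amplified DNA). A linear response
#' `measured = a * nominal + b` is fitted to the standards by least squares
#' and inverted per CpG unit, clamping to \[0, 100\].
#'
#' @param profile Data frame with columns `position` (integer offset to the
#'   TSS) and `raw_pct` (measured methylation, percent); an `amplicon_id`
#'   column is carried through if present.
#' @param standards Data frame with columns `nominal_pct` and
#'   `measured_pct`, spanning at least 2 distinct nominal levels.
#' @return The profile with a `norm_pct` column added.
#' @export
normalize_methylation <- function(profile, standards) {
  stopifnot(is.data.frame(profile),
            all(c("position", "raw_pct") %in% names(profile)),
            is.data.frame(standards),
            all(c("nominal_pct", "measured_pct") %in% names(standards)))
  if (length(unique(standards$nominal_pct)) < 2L) {
    stop("methylation standards must span at least 2 nominal levels")
  }
  if (any(profile$raw_pct < 0 | profile$raw_pct > 100)) {
    stop("raw_pct must lie in [0, 100]")
  }
  fit <- stats::lm(measured_pct ~ nominal_pct, data = standards)
  a <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  if (abs(a) < 1e-6) stop("uninformative standards: fitted gain is ~0")
  norm <- (profile$raw_pct - b) / a
  n_clamped <- sum(norm < -1e-9 | norm > 100 + 1e-9)
  if (n_clamped > 0L) {
    warning(n_clamped, " normalized value(s) outside [0, 100] clamped")
  }
  profile$norm_pct <- pmin(pmax(norm, 0), 100)
  profile
}

#' Construct a bisulfite clone matrix
#'
#' Single cloned bisulfite amplicons give per-molecule CpG methylation
#' calls. Each clone carries a call vector over shared CpG positions
#' (`"M"` methylated, `"U"` unmethylated, `NA`/`"."` missing) and, where a
#' heterozygous phasing SNP lies inside the amplicon, an allele label that
#' assigns the molecule to one parental allele.
#'
#' @param calls Character matrix, clones in rows, CpG positions in columns;
#'   column names are integer offsets to the TSS; values `"M"`, `"U"`,
#'   `"."` or `NA`.
#' @param allele Character vector, one of `"A"`, `"B"`, `"unknown"` per
#'   clone.
#' @return Object of class `"clone_matrix"`.
#' @export
bisulfite_clone_matrix <- function(calls, allele) {
  stopifnot(is.matrix(calls), nrow(calls) >= 1L, ncol(calls) >= 1L)
  calls[calls == "."] <- NA_character_
  if (!all(calls %in% c("M", "U", NA_character_))) {
    stop("CpG calls must be 'M', 'U' or missing ('.'/NA)")
  }
  pos <- suppressWarnings(as.integer(colnames(calls)))
  if (any(is.na(pos))) {
    stop("column names of `calls` must be integer CpG positions (TSS offsets)")
  }
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("CpG positions must be strictly increasing")
  }
  allele <- as.character(allele)
  if (length(allele) != nrow(calls)) {
    stop("`allele` must have one entry per clone")
  }
  if (!all(allele %in% c("A", "B", "unknown"))) {
    stop("allele labels must be 'A', 'B' or 'unknown'")
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("clone", seq_len(nrow(calls)))
  }
  structure(list(calls = calls, allele = allele, positions = pos),
            class = "clone_matrix")
}

#' @export
print.clone_matrix <- function(x, ...) {
  cat(sprintf(
    "Bisulfite clone matrix: %d clones x %d CpGs (positions %+d..%+d); alleles: %s\n",
    nrow(x$calls), ncol(x$calls), min(x$positions), max(x$positions),
    paste(sprintf("%s=%d", names(table(x$allele)), table(x$allele)),
          collapse = ", ")))
  invisible(x)
}

#' Split a clone matrix by the phasing-SNP allele
#'
#' Partitions clones into the two allele groups; clones with an unknown
#' allele call are excluded and their count reported via a message.
#'
#' @param m A `"clone_matrix"`.
#' @return List with `A` and `B` (clone matrices) and `n_excluded`.
#' @export
split_clones_by_allele <- function(m) {
  stopifnot(inherits(m, "clone_matrix"))
  known <- m$allele %in% c("A", "B")
  if (!any(known)) {
    stop("no informative SNP for allelic separation: ",
         "all clones carry an unknown allele call")
  }
  n_excluded <- sum(!known)
  if (n_excluded > 0L) {
    message(n_excluded, " clone(s) with unknown allele excluded")
  }
  sub <- function(which_allele) {
    idx <- m$allele == which_allele
    if (!any(idx)) return(NULL)
    bisulfite_clone_matrix(m$calls[idx, , drop = FALSE],
                           m$allele[idx])
  }
  list(A = sub("A"), B = sub("B"), n_excluded = n_excluded)
}

#' Pooled methylation level over a promoter window
#'
#' The methylation level of a region is the percentage of methylated calls
#' among all non-missing CpG calls pooled across clones and CpG positions
#' inside the closed interval `[start, end]` (box counting over the clone
#' display; robust to clones with many missing calls).
#'
#' @param m A `"clone_matrix"`.
#' @param start,end Window bounds as TSS offsets (closed interval).
#' @return Methylation percentage in \[0, 100\].
#' @export
region_methylation <- function(m, start, end) {
  stopifnot(inherits(m, "clone_matrix"), start <= end)
  in_win <- m$positions >= start & m$positions <= end
  if (!any(in_win)) stop("no covered CpG in [", start, ", ", end, "]")
  calls <- m$calls[, in_win, drop = FALSE]
  n_m <- sum(calls == "M", na.rm = TRUE)
  n_obs <- sum(!is.na(calls))
  if (n_obs == 0L) stop("no covered CpG in [", start, ", ", end,
                        "] (all calls missing)")
  100 * n_m / n_obs
}

#' Compare methylation between two sample groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with group medians,
#' applied e.g. per amplicon or per CpG unit to allele-imbalanced versus
#' balanced samples.
#'
#' @param group1,group2 Numeric vectors of methylation values (>= 2 each).
#' @return List with `p`, `median1`, `median2`.
#' @export
compare_group_methylation <- function(group1, group2) {
  stopifnot(length(group1) >= 2L, length(group2) >= 2L)
  pooled <- c(group1, group2)
  if (all(pooled == pooled[1L])) {
    warning("constant pooled data: no distributional difference testable")
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(group1, group2, alternative = "two.sided"))$p.value
  }
  list(p = p,
       median1 = stats::median(group1),
       median2 = stats::median(group2))
}

#' Allele-specific methylation by methylation-specific SNuPE (ASM-SNuPE)
#'
#' Methylated and unmethylated alleles are amplified separately from
#' bisulfite-converted DNA (MSP/UMSP) and the phasing SNP is genotyped in
#' each amplicon by primer extension. A CpG dinucleotide inside each
#' amplicon serves as specificity control: the methylation-specific
#' amplicon must read (nearly) fully methylated and the
#' unmethylated-specific amplicon (nearly) fully unmethylated there,
#' otherwise the amplification was not allele-pure and the genotype split
#' is not evaluable. Given a clean control, a large difference between the
#' two amplicons' reference-allele fractions indicates that methylation
#' segregates with one allele.
#'
#' @param meth_pair,unmeth_pair Lists (or one-row data frames) with
#'   `intensity_ref` and `intensity_alt`: the SNP peak pair measured in the
#'   methylated-specific and unmethylated-specific amplicon.
#' @param control_m_frac Named numeric vector
#'   `c(meth = ..., unmeth = ...)`: methylated fraction read at the control
#'   CpG in each amplicon.
#' @param purity_threshold Control CpG must be at least this methylated in
#'   the M amplicon and at most `1 - purity_threshold` in the U amplicon;
#'   default 0.9.
#' @param asm_margin Minimum absolute difference between the two amplicons'
#'   reference-allele fractions to call ASM; default 0.3.
#' @return Object of class `"asm_snupe_result"`: list with
#'   `geno_fraction_meth`, `geno_fraction_unmeth`, `control_ok`,
#'   `asm_positive` (NA when the control fails).
#' @export
asm_snupe <- function(meth_pair, unmeth_pair, control_m_frac,
                      purity_threshold = 0.9, asm_margin = 0.3) {
  stopifnot(all(c("meth", "unmeth") %in% names(control_m_frac)),
            purity_threshold > 0.5, purity_threshold <= 1,
            asm_margin >= 0, asm_margin < 1)
  gm <- allelic_fraction(meth_pair$intensity_ref, meth_pair$intensity_alt)
  gu <- allelic_fraction(unmeth_pair$intensity_ref, unmeth_pair$intensity_alt)
  control_ok <- control_m_frac[["meth"]] >= purity_threshold &&
    control_m_frac[["unmeth"]] <= 1 - purity_threshold
  asm_positive <- if (control_ok) abs(gm - gu) > asm_margin else NA
  structure(
    list(geno_fraction_meth = gm, geno_fraction_unmeth = gu,
         control_ok = control_ok, asm_positive = asm_positive,
         purity_threshold = purity_threshold, asm_margin = asm_margin),
    class = "asm_snupe_result")
}

#' @export
print.asm_snupe_result <- function(x, ...) {
  cat(sprintf(
    "ASM-SNuPE: ref-allele fraction %.3f (methylated amplicon) vs %.3f (unmethylated); control %s; ASM %s\n",
    x$geno_fraction_meth, x$geno_fraction_unmeth,
    if (x$control_ok) "clean" else "FAILED",
    if (is.na(x$asm_positive)) "not evaluable"
    else if (x$asm_positive) "POSITIVE" else "negative"))
  invisible(x)
}
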