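# Readers/writers for the TSV schemas and the end-to-end pipeline.
# All files are UTF-8, tab-separated, header row, '.' for missing values.

PEAKS_COLUMNS <- c("sample_id", "snp_id", "analyte", "replicate",
                   "allele_ref", "allele_alt",
                   "intensity_ref", "intensity_alt")
ANALYTES <- c("cdna", "gdna", "bt_unmeth", "bt_meth")

validate_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  missing_cols <- setdiff(PEAKS_COLUMNS, names(peaks))
  if (length(missing_cols) > 0L) {
    stop("peak table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(peaks$analyte %in% ANALYTES)) {
    bad <- unique(setdiff(peaks$analyte, ANALYTES))
    stop("unknown analyte value(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(ANALYTES, collapse = "/"), ")")
  }
  for (col in c("intensity_ref", "intensity_alt")) {
    if (!is.numeric(peaks[[col]])) {
      stop("column ", col, " must be numeric")
    }
    if (any(peaks[[col]] < 0, na.rm = TRUE)) {
      stop("column ", col, " contains negative intensities")
    }
  }
  if (any(peaks$allele_ref == peaks$allele_alt)) {
    stop("allele_ref must differ from allele_alt")
  }
  key <- paste(peaks$sample_id, peaks$snp_id, peaks$analyte, peaks$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate replicate index within (sample_id, snp_id, analyte)")
  }
  peaks
}

validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(c("sample_id", "group", "fraction"), names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(cohort$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'")
  }
  if (!is.numeric(cohort$fraction) ||
      any(cohort$fraction < 0 | cohort$fraction > 1, na.rm = TRUE)) {
    stop("fraction must be numeric in [0, 1]")
  }
  cohort
}

read_tsv_checked <- function(path, required, numeric_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = ".",
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in numeric_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(conv))
      if (length(bad) > 0L) {
        stop("row error in ", basename(path), ": non-numeric ", col,
             " at data row(s) ", paste(utils::head(bad, 5), collapse = ", "))
      }
      df[[col]] <- conv
    }
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a peak-intensity table (`peaks.tsv` schema)
#'
#' Expected columns: `sample_id`, `snp_id`, `analyte`
#' (cdna/gdna/bt_unmeth/bt_meth), `replicate`, `allele_ref`, `allele_alt`,
#' `intensity_ref`, `intensity_alt`. Malformed rows and unknown analytes
#' are rejected with informative errors.
#'
#' @param path Path to a UTF-8 tab-separated file with a header row.
#' @return Validated peak data frame.
#' @export
read_peaks <- function(path) {
  df <- read_tsv_checked(path, PEAKS_COLUMNS,
                         numeric_cols = c("replicate", "intensity_ref",
                                          "intensity_alt"))
  validate_peaks(df[PEAKS_COLUMNS])
}

#' Write a peak-intensity table
#' @param peaks Peak data frame (validated against the `peaks.tsv` schema).
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  write_tsv(validate_peaks(peaks)[PEAKS_COLUMNS], path)
}

#' Read a cohort table (`cohort.tsv` schema)
#' @param path Path to a tab-separated file with columns `sample_id`,
#'   `group` (case/control), `fraction`.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "group", "fraction"),
                         numeric_cols = "fraction")
  validate_cohort(df[c("sample_id", "group", "fraction")])
}

#' Write a cohort table
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  write_tsv(validate_cohort(cohort)[c("sample_id", "group", "fraction")],
            path)
}

#' Read a bisulfite clone table (`clones.tsv` schema)
#'
#' Columns: `clone_id`, `allele` (A/B/unknown), then one column per CpG
#' position whose header is the integer TSS offset; values `M`, `U` or `.`.
#'
#' @param path Path to the TSV.
#' @return A `"clone_matrix"`.
#' @export
read_clones <- function(path) {
  df <- read_tsv_checked(path, c("clone_id", "allele"))
  cpg_cols <- setdiff(names(df), c("clone_id", "allele"))
  if (length(cpg_cols) == 0L) stop("no CpG columns in ", basename(path))
  calls <- as.matrix(df[cpg_cols])
  mode(calls) <- "character"
  rownames(calls) <- df$clone_id
  colnames(calls) <- cpg_cols
  bisulfite_clone_matrix(calls, df$allele)
}

#' Write a bisulfite clone table
#' @param m A `"clone_matrix"`.
#' @param path Output path.
#' @export
write_clones <- function(m, path) {
  stopifnot(inherits(m, "clone_matrix"))
  df <- data.frame(clone_id = rownames(m$calls), allele = m$allele,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(m$positions)) {
    df[[as.character(m$positions[j])]] <- m$calls[, j]
  }
  write_tsv(df, path)
}

config_hash <- function(config) {
  # order-independent polynomial rolling hash over the deparsed config
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 17
  for (b in utf8ToInt(txt)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Run the end-to-end ASE pipeline: quantify, correct, call, report
#'
#' Aggregates replicate peak pairs into allelic fractions, pairs each
#' sample's cDNA fraction with its gDNA fraction and applies the gDNA
#' correction (samples outside the heterozygosity band are dropped with a
#' warning), runs both cohort callers and the screening tests, and writes
#' `fractions.tsv`, `corrected.tsv`, `calls.tsv`, `thresholds.json` and
#' `report.txt` to `out_dir`. Deterministic given identical inputs and
#' configuration.
#'
#' @param peaks Peak data frame or path to a `peaks.tsv` file holding
#'   `cdna` and `gdna` analyte rows per sample.
#' @param groups Data frame or TSV path with columns `sample_id` and
#'   `group` (case/control).
#' @param out_dir Output directory (created if absent).
#' @param snp_id SNP assay to analyse; default the single SNP present.
#' @param alpha Alpha-outlier level; default 0.05.
#' @param huber_k Huber tuning constant; default 1.345.
#' @param min_total_intensity Replicate QC threshold; default 0.
#' @param het_band Heterozygosity band for informative gDNA; default
#'   `c(0.3, 0.7)`.
#' @return Invisibly, a list with `cohort`, `calls` (per method),
#'   `screening`, `paths`.
#' @export
run_pipeline <- function(peaks, groups, out_dir,
                         snp_id = NULL, alpha = 0.05, huber_k = 1.345,
                         min_total_intensity = 0, het_band = c(0.3, 0.7)) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.character(peaks)) peaks <- stage("quantify", read_peaks(peaks))
  if (is.character(groups)) {
    groups <- stage("quantify",
                    read_tsv_checked(groups, c("sample_id", "group")))
  }
  config <- list(snp_id = snp_id, alpha = alpha, huber_k = huber_k,
                 min_total_intensity = min_total_intensity,
                 het_band = het_band)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fractions <- stage("quantify",
                     aggregate_replicates(peaks, min_total_intensity))
  if (is.null(snp_id)) {
    snp_id <- unique(fractions$snp_id)
    if (length(snp_id) != 1L) {
      stop("quantify: several SNPs present; choose one via snp_id")
    }
  }
  fr <- fractions[fractions$snp_id == snp_id, , drop = FALSE]

  corrected <- stage("correct", {
    cdna <- fr[fr$analyte == "cdna", c("sample_id", "fraction")]
    gdna <- fr[fr$analyte == "gdna", c("sample_id", "fraction")]
    names(cdna)[2] <- "f_cdna"
    names(gdna)[2] <- "f_gdna"
    cc <- merge(cdna, gdna, by = "sample_id")
    if (nrow(cc) == 0L) stop("no samples with both cDNA and gDNA fractions")
    informative <- cc$f_gdna >= het_band[1] & cc$f_gdna <= het_band[2]
    if (any(!informative)) {
      warning(sum(!informative), " sample(s) outside the heterozygosity ",
              "band excluded from cohort calling")
    }
    cc$f_corrected <- NA_real_
    cc$f_corrected[informative] <- suppressWarnings(
      correct_by_gdna(cc$f_cdna[informative], cc$f_gdna[informative],
                      het_band))
    cc$informative <- informative
    cc[order(cc$sample_id), ]
  })

  cohort <- stage("ase_calling", {
    co <- merge(corrected[corrected$informative,
                          c("sample_id", "f_corrected")],
                groups, by = "sample_id")
    names(co)[names(co) == "f_corrected"] <- "fraction"
    if (!any(co$group == "case")) stop("no cases")
    validate_cohort(co[c("sample_id", "group", "fraction")])
  })
  cohort <- cohort[order(cohort$sample_id), ]

  calls <- stage("ase_calling", {
    list(youden = call_ase(cohort, "youden", huber_k = huber_k),
         alpha_outlier = call_ase(cohort, "alpha_outlier", alpha = alpha,
                                  huber_k = huber_k))
  })
  screening <- stage("ase_calling", screening_tests(cohort))

  paths <- stage("report", {
    p <- list(
      fractions = file.path(out_dir, "fractions.tsv"),
      corrected = file.path(out_dir, "corrected.tsv"),
      calls = file.path(out_dir, "calls.tsv"),
      thresholds = file.path(out_dir, "thresholds.json"),
      report = file.path(out_dir, "report.txt")
    )
    write_tsv(fractions, p$fractions)
    write_tsv(corrected[c("sample_id", "f_cdna", "f_gdna", "f_corrected")],
              p$corrected)
    calls_df <- data.frame(
      sample_id = cohort$sample_id, group = cohort$group,
      fraction = cohort$fraction,
      youden_flag = unname(calls$youden$flags[cohort$sample_id]),
      alpha_flag = unname(calls$alpha_outlier$flags[cohort$sample_id]),
      stringsAsFactors = FALSE
    )
    write_tsv(calls_df, p$calls)
    thresholds <- list(
      youden = list(method = "youden",
                    lower = calls$youden$lower_cutoff,
                    upper = calls$youden$upper_cutoff),
      alpha_outlier = list(method = "alpha_outlier",
                           lower = calls$alpha_outlier$lower_cutoff,
                           upper = calls$alpha_outlier$upper_cutoff,
                           location = calls$alpha_outlier$estimates$location,
                           scale = calls$alpha_outlier$estimates$scale,
                           alpha = alpha)
    )
    jsonlite::write_json(thresholds, p$thresholds, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    n_case <- sum(cohort$group == "case")
    n_ctrl <- sum(cohort$group == "control")
    lines <- c(
      "ASE pipeline report",
      sprintf("config %s  (snp %s, alpha %.3f, huber_k %.3f)",
              config_hash(config), snp_id, alpha, huber_k),
      sprintf("cohort: %d cases, %d controls (informative heterozygotes)",
              n_case, n_ctrl),
      sprintf("Youden cutoffs: [%.4f, %.4f]; positive: %d/%d cases (%.1f%%), %d controls",
              calls$youden$lower_cutoff, calls$youden$upper_cutoff,
              calls$youden$n_positive, n_case,
              100 * calls$youden$n_positive / n_case,
              calls$youden$n_positive_controls),
      sprintf("alpha-outlier limits (alpha %.2f): [%.4f, %.4f]; positive: %d/%d cases (%.1f%%), %d controls",
              alpha, calls$alpha_outlier$lower_cutoff,
              calls$alpha_outlier$upper_cutoff,
              calls$alpha_outlier$n_positive, n_case,
              100 * calls$alpha_outlier$n_positive / n_case,
              calls$alpha_outlier$n_positive_controls),
      sprintf("Huber M-estimates (cases): location %.4f, scale %.4f",
              calls$alpha_outlier$estimates$location,
              calls$alpha_outlier$estimates$scale),
      sprintf("screening: Mann-Whitney p = %.4g (medians %.3f vs %.3f), F-test p = %.4g",
              screening$mw_p, screening$median_case,
              screening$median_control, screening$f_test_p)
    )
    writeLines(lines, p$report)
    p
  })

  invisible(list(cohort = cohort, calls = calls, screening = screening,
                 corrected = corrected, paths = paths))
}
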