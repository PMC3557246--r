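# Shared helpers: small fixture builders and independent oracles.

# Build a peak table from per-replicate intensity pairs.
make_peaks <- function(pairs, sample_id = "S1", snp_id = "rs1056719",
                       analyte = "cdna") {
  data.frame(
    sample_id = sample_id, snp_id = snp_id, analyte = analyte,
    replicate = seq_len(nrow(pairs)),
    allele_ref = "G", allele_alt = "A",
    intensity_ref = pairs[, 1], intensity_alt = pairs[, 2],
    stringsAsFactors = FALSE
  )
}

# Independent brute-force Youden maximization: counting loops over a
# cutoff grid that brackets every data point from both sides, restricted
# per direction at the control median. Returns the achieved maximal J per
# direction (NA when a direction has no admissible cutoff).
brute_force_youden <- function(cases, controls) {
  med <- stats::median(controls)
  pts <- sort(unique(c(cases, controls)))
  eps <- min(diff(pts), 1) / 4
  grid <- sort(unique(c(pts - eps, pts + eps,
                        (pts[-1] + pts[-length(pts)]) / 2)))
  j_at <- function(c, direction) {
    sens <- 0
    for (x in cases) {
      if (direction == "low" && x < c) sens <- sens + 1
      if (direction == "high" && x > c) sens <- sens + 1
    }
    spec <- 0
    for (x in controls) {
      if (direction == "low" && x >= c) spec <- spec + 1
      if (direction == "high" && x <= c) spec <- spec + 1
    }
    sens / length(cases) + spec / length(controls) - 1
  }
  low_grid <- grid[grid < med & grid > min(pts)]
  high_grid <- grid[grid > med & grid < max(pts)]
  list(
    j_low = if (length(low_grid) == 0) NA_real_ else
      max(vapply(low_grid, j_at, numeric(1), direction = "low")),
    j_high = if (length(high_grid) == 0) NA_real_ else
      max(vapply(high_grid, j_at, numeric(1), direction = "high"))
  )
}
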