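test_that("methylation normalization inverts a known linear distortion exactly", {
  standards <- data.frame(nominal_pct = c(0, 20, 40, 60, 80, 100),
                          measured_pct = 0.8 * c(0, 20, 40, 60, 80, 100) + 5)
  profile <- data.frame(position = c(-100, 50, 200),
                        raw_pct = c(45, 21, 85))
  out <- normalize_methylation(profile, standards)
  expect_equal(out$norm_pct, c((45 - 5) / 0.8, (21 - 5) / 0.8, 100))
  expect_equal(out$norm_pct[1], 50)

  # identity standards leave the profile untouched
  id_std <- data.frame(nominal_pct = c(0, 20, 40, 60, 80, 100),
                       measured_pct = c(0, 20, 40, 60, 80, 100))
  out_id <- normalize_methylation(profile, id_std)
  expect_equal(out_id$norm_pct, profile$raw_pct)

  # normalizing the standards themselves recovers the nominal levels
  self <- normalize_methylation(
    data.frame(position = 1:6, raw_pct = standards$measured_pct), standards)
  expect_equal(self$norm_pct, standards$nominal_pct, tolerance = 1e-10)
  expect_true(all(diff(self$norm_pct) > 0))  # monotone
})

test_that("out-of-range normalized values are clamped with a warning", {
  standards <- data.frame(nominal_pct = c(0, 50, 100),
                          measured_pct = c(10, 55, 95))
  expect_warning(
    out <- normalize_methylation(
      data.frame(position = 1, raw_pct = 99), standards),
    "clamped")
  expect_equal(out$norm_pct, 100)
  flat <- data.frame(nominal_pct = c(0, 50, 100), measured_pct = rep(40, 3))
  expect_error(normalize_methylation(
    data.frame(position = 1, raw_pct = 40), flat), "uninformative standards")
})

test_that("clone matrices split by phasing-SNP allele with exclusion accounting", {
  calls <- matrix(rep(c("M", "U"), 30), nrow = 12, ncol = 5)
  colnames(calls) <- c(58, 100, 150, 200, 263)
  m <- bisulfite_clone_matrix(calls, c(rep("A", 5), rep("B", 7)))
  sp <- split_clones_by_allele(m)
  expect_equal(nrow(sp$A$calls), 5L)
  expect_equal(nrow(sp$B$calls), 7L)
  expect_equal(sp$n_excluded, 0L)

  m2 <- bisulfite_clone_matrix(calls, c(rep("A", 5), rep("B", 5),
                                        rep("unknown", 2)))
  expect_message(sp2 <- split_clones_by_allele(m2), "2 clone")
  expect_equal(sp2$n_excluded, 2L)

  m3 <- bisulfite_clone_matrix(calls, rep("unknown", 12))
  expect_error(split_clones_by_allele(m3),
               "no informative SNP for allelic separation")
})

test_that("region methylation pools M calls over non-missing calls in the window", {
  calls <- rbind(c("M", "M", "U", NA),
                 c("M", "U", "U", "U"),
                 c(NA, "U", "M", "U"))
  colnames(calls) <- c(58, 120, 200, 300)
  m <- bisulfite_clone_matrix(calls, rep("A", 3))
  expect_equal(region_methylation(m, 58, 263), 4 / 8 * 100)
  expect_equal(region_methylation(m, 58, 300), 4 / 10 * 100)
  all_m <- bisulfite_clone_matrix(
    matrix("M", 2, 3, dimnames = list(NULL, c(1, 2, 3))), rep("A", 2))
  expect_equal(region_methylation(all_m, 1, 3), 100)
  expect_error(region_methylation(m, 400, 500), "no covered CpG")
})

test_that("region methylation is invariant to clone order and all-missing clones", {
  m <- simulate_bisulfite_clones(10, 0.8, 0.3, 8, seed = 3)
  v <- region_methylation(m, 58, 263)
  perm <- withr::with_seed(4, sample(nrow(m$calls)))
  m_perm <- bisulfite_clone_matrix(m$calls[perm, ], m$allele[perm])
  expect_equal(region_methylation(m_perm, 58, 263), v)
  extra <- rbind(m$calls, matrix(NA_character_, 1, ncol(m$calls)))
  m_extra <- bisulfite_clone_matrix(extra, c(m$allele, "A"))
  expect_equal(region_methylation(m_extra, 58, 263), v)
})

test_that("full-matrix methylation equals the clone-weighted blend of allele splits", {
  m <- simulate_bisulfite_clones(12, 0.85, 0.25, 10, missing_rate = 0.1,
                                 seed = 8)
  sp <- split_clones_by_allele(m)
  win <- c(58, 263)
  n_a <- sum(!is.na(sp$A$calls))
  n_b <- sum(!is.na(sp$B$calls))
  blended <- (region_methylation(sp$A, win[1], win[2]) * n_a +
              region_methylation(sp$B, win[1], win[2]) * n_b) / (n_a + n_b)
  expect_equal(region_methylation(m, win[1], win[2]), blended)
})

test_that("group methylation comparison reproduces exact Mann-Whitney p-values", {
  res <- compare_group_methylation(1:7, 8:14)
  expect_equal(res$p, 2 / choose(14, 7))  # most extreme assignment, two-sided
  expect_equal(res$p, 0.000583, tolerance = 1e-3)
  expect_equal(res$median1, 4)
  expect_equal(res$median2, 11)

  same <- compare_group_methylation(c(10, 20, 30), c(10, 20, 30))
  expect_gt(same$p, 0.99)
  expect_warning(res_const <- compare_group_methylation(rep(5, 3), rep(5, 4)),
                 "constant pooled data")
  expect_equal(res_const$p, 1)
})

test_that("a planted methylation shift between imbalance groups is detected", {
  # 7 most imbalanced vs 7 most balanced samples, intron-1 methylation
  imbalanced <- withr::with_seed(15, rnorm(7, 45, 8))
  balanced <- withr::with_seed(16, rnorm(7, 15, 8))
  res <- compare_group_methylation(imbalanced, balanced)
  expect_lt(res$p, 0.01)
})

test_that("ASM-SNuPE calls allele-specific methylation only with a clean control", {
  res <- asm_snupe(
    meth_pair = list(intensity_ref = 2, intensity_alt = 98),
    unmeth_pair = list(intensity_ref = 97, intensity_alt = 3),
    control_m_frac = c(meth = 0.98, unmeth = 0.02))
  expect_true(res$control_ok)
  expect_true(res$asm_positive)

  balanced <- asm_snupe(
    meth_pair = list(intensity_ref = 50, intensity_alt = 50),
    unmeth_pair = list(intensity_ref = 50, intensity_alt = 50),
    control_m_frac = c(meth = 1, unmeth = 0))
  expect_true(balanced$control_ok)
  expect_false(balanced$asm_positive)

  impure <- asm_snupe(
    meth_pair = list(intensity_ref = 2, intensity_alt = 98),
    unmeth_pair = list(intensity_ref = 97, intensity_alt = 3),
    control_m_frac = c(meth = 0.98, unmeth = 0.5))
  expect_false(impure$control_ok)
  expect_true(is.na(impure$asm_positive))
})

test_that("ASM-SNuPE is symmetric under a joint allele-label swap", {
  res1 <- asm_snupe(list(intensity_ref = 10, intensity_alt = 90),
                    list(intensity_ref = 80, intensity_alt = 20),
                    c(meth = 0.95, unmeth = 0.05))
  res2 <- asm_snupe(list(intensity_ref = 90, intensity_alt = 10),
                    list(intensity_ref = 20, intensity_alt = 80),
                    c(meth = 0.95, unmeth = 0.05))
  expect_equal(res1$asm_positive, res2$asm_positive)
  expect_equal(res1$geno_fraction_meth, 1 - res2$geno_fraction_meth)
})
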