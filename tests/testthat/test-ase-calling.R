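test_that("Huber M-estimates are consistent at the normal model", {
  x <- withr::with_seed(123, rnorm(10000))
  est <- huber_m(x)
  expect_true(est$converged)
  expect_equal(est$location, 0, tolerance = 0.05)
  expect_equal(est$scale, 1, tolerance = 0.05)
})

test_that("Huber M-estimates resist gross contamination", {
  x <- withr::with_seed(5, c(rnorm(110, 0.40, 0.01), rep(0.9, 10)))
  est <- huber_m(x)
  expect_equal(est$location, 0.40, tolerance = 0.01)
  # cross-check against the reference iterative-reweighting implementation
  skip_if_not_installed("MASS")
  ref <- MASS::hubers(x, k = 1.345)
  expect_equal(est$location, ref$mu, tolerance = 1e-3)
  expect_equal(est$scale, ref$s, tolerance = 0.05 * ref$s)
})

test_that("Huber location shifts by less than half a scale under 10% contamination", {
  base <- withr::with_seed(21, rnorm(100, 0.4, 0.05))
  est0 <- huber_m(base)
  for (shift in c(10, -10)) {
    contaminated <- c(base[1:90], base[91:100] + shift * est0$scale)
    est1 <- huber_m(contaminated)
    expect_lt(abs(est1$location - est0$location), 0.5 * est0$scale)
  }
})

test_that("Huber M converges to mean and SD as the tuning constant grows", {
  x <- withr::with_seed(9, rnorm(200, 3, 2))
  est <- huber_m(x, tuning_k = 1e6)
  expect_equal(est$location, mean(x), tolerance = 1e-6)
  expect_equal(est$scale, sd(x), tolerance = 1e-6)
})

test_that("Huber M handles degenerate and tiny inputs", {
  est <- huber_m(rep(0.4, 10))
  expect_equal(est$location, 0.4)
  expect_equal(est$scale, 0)
  expect_true(est$degenerate)
  expect_error(huber_m(c(1, 2)), "at least 3")
})

test_that("alpha-outlier limits are the central normal quantile band", {
  lim <- alpha_outlier_limits(list(location = 0, scale = 1), alpha = 0.05)
  expect_equal(unname(lim), c(-1, 1) * qnorm(0.975), tolerance = 1e-10)
  expect_equal(unname(lim), c(-1.9600, 1.9600), tolerance = 1e-4)

  lim2 <- alpha_outlier_limits(list(location = 0.40, scale = 0.08),
                               alpha = 0.05)
  expect_equal(unname(lim2), c(0.2432, 0.5568), tolerance = 1e-4)

  lim3 <- alpha_outlier_limits(list(location = 0, scale = 1), alpha = 0.32)
  expect_equal(unname(lim3), c(-0.9945, 0.9945), tolerance = 1e-4)

  expect_error(alpha_outlier_limits(list(location = 0.4, scale = 0)),
               "degenerate scale")
})

test_that("alpha-outlier flag rate on pure-null cohorts is close to alpha", {
  rates <- withr::with_seed(77, vapply(1:200, function(i) {
    x <- rnorm(120, 0.4, 0.05)
    est <- huber_m(x)
    lim <- alpha_outlier_limits(est, 0.05)
    mean(x < lim[["lower"]] | x > lim[["upper"]])
  }, numeric(1)))
  expect_lt(abs(mean(rates) - 0.05), 0.015)
})

test_that("Youden cutoffs match the exhaustive brute-force oracle on small instances", {
  set.seed(31)
  for (i in 1:25) {
    n_cases <- sample(4:15, 1)
    n_controls <- sample(c(5, 7, 9, 11, 13), 1)  # odd: median is a data point
    cases <- round(c(rnorm(n_cases, 0.4, 0.05),
                     if (i %% 2 == 0) runif(2, 0.6, 0.9)), 4)
    controls <- round(rnorm(n_controls, 0.43, 0.03), 4)
    got <- youden_cutoffs(cases, controls)
    oracle <- brute_force_youden(cases, controls)
    if (!is.na(oracle$j_low) && oracle$j_low > 0) {
      expect_equal(got$j_lower, oracle$j_low, tolerance = 1e-12)
      expect_equal(mean(cases < got$lower) + mean(controls >= got$lower) - 1,
                   oracle$j_low, tolerance = 1e-12)
    }
    if (!is.na(oracle$j_high) && oracle$j_high > 0) {
      expect_equal(got$j_upper, oracle$j_high, tolerance = 1e-12)
      expect_equal(mean(cases > got$upper) + mean(controls <= got$upper) - 1,
                   oracle$j_high, tolerance = 1e-12)
    }
  }
})

test_that("Youden cutoffs bracket planted extremes around a shared bulk", {
  controls <- seq(0.40, 0.46, by = 0.01)
  cases <- c(controls, 0.10, 0.90)
  got <- youden_cutoffs(cases, controls)
  expect_gt(got$lower, 0.10)
  expect_lt(got$lower, 0.40)
  expect_gt(got$upper, 0.46)
  expect_lt(got$upper, 0.90)
  expect_true(0.10 < got$lower && 0.90 > got$upper)  # extremes flagged
})

test_that("identical case and control samples give degenerate sentinels", {
  x <- c(0.38, 0.40, 0.42, 0.44)
  got <- youden_cutoffs(x, x)
  expect_identical(got$lower, -Inf)
  expect_identical(got$upper, Inf)
  expect_equal(got$j_lower, 0)
})

test_that("perfect low-direction separation yields J = 1 at the gap midpoint", {
  cases <- c(0.10, 0.12, 0.15)
  controls <- c(0.40, 0.42, 0.44, 0.46, 0.48)
  got <- youden_cutoffs(cases, controls)
  expect_equal(got$j_lower, 1)
  expect_equal(got$lower, (0.15 + 0.40) / 2)
})

test_that("alpha-outlier caller on fixture B flags exactly the planted extremes", {
  cohort <- cohort_fixture("B")
  planted <- attr(cohort, "planted")
  res <- call_ase(cohort, "alpha_outlier", alpha = 0.05)
  expect_equal(res$n_positive, 10L)
  expect_true(all(res$flags[cohort$sample_id[planted]]))
  expect_false(any(res$flags[cohort$sample_id[!planted]]))
  expect_equal(res$estimates$location, 0.40, tolerance = 0.02)
})

test_that("call_ase flags are strict and invariant under reordering and duplication", {
  cohort <- cohort_fixture("B")
  res <- call_ase(cohort, "alpha_outlier")
  # strict inequality: a sample exactly on a cutoff is negative
  on_cut <- data.frame(sample_id = "edge", group = "case",
                       fraction = res$lower_cutoff)
  cohort2 <- rbind(cohort, on_cut)
  # reorder
  perm <- withr::with_seed(2, sample(nrow(cohort)))
  res_perm <- call_ase(cohort[perm, ], "alpha_outlier")
  expect_equal(res_perm$flags[names(res$flags)], res$flags)
  expect_equal(res_perm$lower_cutoff, res$lower_cutoff)
  # duplication of the full cohort leaves thresholds unchanged
  dup <- cohort
  dup$sample_id <- paste0(dup$sample_id, "_b")
  res_dup <- call_ase(rbind(cohort, dup), "alpha_outlier")
  # scale carries an n-1 divisor, so invariance is exact up to O(1/n)
  expect_equal(res_dup$lower_cutoff, res$lower_cutoff, tolerance = 0.005)
  expect_equal(res_dup$upper_cutoff, res$upper_cutoff, tolerance = 0.005)
  expect_equal(res_dup$n_positive, 2L * res$n_positive)
  # same for the Youden caller (fixture A carries controls)
  ca <- cohort_fixture("A")
  resy <- call_ase(ca, "youden")
  dupa <- ca
  dupa$sample_id <- paste0(dupa$sample_id, "_b")
  resy_dup <- call_ase(rbind(ca, dupa), "youden")
  expect_equal(resy_dup$lower_cutoff, resy$lower_cutoff)
  expect_equal(resy_dup$upper_cutoff, resy$upper_cutoff)
})

test_that("a perfectly balanced cohort yields no calls and a degenerate scale error", {
  cohort <- data.frame(
    sample_id = sprintf("s%02d", 1:20),
    group = rep(c("case", "control"), each = 10),
    fraction = rep(0.5, 20))
  res <- call_ase(cohort, "youden")
  expect_equal(res$n_positive, 0L)
  expect_identical(res$lower_cutoff, -Inf)
  expect_error(call_ase(cohort, "alpha_outlier"), "degenerate scale")
})

test_that("screening tests reproduce exact rank-based p-values", {
  cohort <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    group = rep(c("case", "control"), each = 3),
    fraction = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  st <- screening_tests(cohort)
  expect_equal(st$mw_p, 0.1)  # exact enumeration over all 20 assignments
  expect_equal(st$median_case, 0.2)
  expect_equal(st$median_control, 0.5)

  same <- data.frame(sample_id = sprintf("s%d", 1:8),
                     group = rep(c("case", "control"), each = 4),
                     fraction = rep(c(0.2, 0.3, 0.4, 0.5), 2))
  st_same <- screening_tests(same)
  expect_gt(st_same$mw_p, 0.99)
  expect_equal(st_same$f_test_p, 1)
})

test_that("planted outliers inflate case variance in the F screen", {
  cohort <- cohort_fixture("A")
  st <- screening_tests(cohort)
  expect_lt(st$f_test_p, 0.05)
})

test_that("constant groups make the F screen unavailable with a warning", {
  cohort <- data.frame(sample_id = sprintf("s%d", 1:8),
                       group = rep(c("case", "control"), each = 4),
                       fraction = c(rep(0.4, 4), 0.41, 0.42, 0.43, 0.44))
  expect_warning(st <- screening_tests(cohort), "constant group")
  expect_true(is.na(st$f_test_p))
})
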