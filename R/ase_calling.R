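# Cohort-level ASE calling: robust Huber M-estimates, alpha-outlier
# regions and bidirectional Youden-index cutoffs, plus screening tests.

#' Joint Huber M-estimates of location and scale
#'
#' Huber's Proposal-2 iteration: observations are winsorized at
#' `tuning_k` scale units around the current location, the location is
#' updated as the mean of the winsorized sample and the scale as the
#' winsorized standard deviation divided by the normal-consistency
#' constant \eqn{\beta(k)^{1/2}}, where
#' \eqn{\beta(k) = E[\psi_k(Z)^2]} for a standard normal Z. Initialized at
#' the median and the (normal-consistent) MAD. Resistant to small to
#' moderate amounts of outliers; as \eqn{k \to \infty} it converges to the
#' sample mean and standard deviation.
#'
#' @param values Numeric vector (>= 3 values).
#' @param tuning_k Winsorization constant in scale units; default 1.345
#'   (95% efficiency at the normal model).
#' @param tol Relative convergence tolerance; default 1e-8.
#' @param max_iter Iteration cap; default 100.
#' @return Object of class `"huber_estimates"`: list with `location`,
#'   `scale`, `tuning_k`, `iterations`, `converged`, `degenerate`.
#' @export
huber_m <- function(values, tuning_k = 1.345, tol = 1e-8, max_iter = 100L) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3L) stop("huber_m requires at least 3 values")
  stopifnot(tuning_k > 0, tol > 0, max_iter >= 1L)
  if (all(x == x[1L])) {
    return(structure(
      list(location = x[1L], scale = 0, tuning_k = tuning_k,
           iterations = 0L, converged = TRUE, degenerate = TRUE),
      class = "huber_estimates"))
  }
  mu <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) s <- stats::sd(x)  # >0 here since not all values identical
  k <- tuning_k
  # E[psi_k(Z)^2] under N(0,1), psi_k = clamping at +-k
  beta <- (2 * stats::pnorm(k) - 1) - 2 * k * stats::dnorm(k) +
    2 * k^2 * (1 - stats::pnorm(k))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    y <- pmin(pmax(x, mu - k * s), mu + k * s)
    mu1 <- mean(y)
    s1 <- sqrt(sum((y - mu1)^2) / ((n - 1) * beta))
    if (s1 == 0) {  # all mass winsorized onto one point
      mu <- mu1; s <- 0
      break
    }
    done <- abs(mu1 - mu) < tol * s1 && abs(s1 - s) < tol * s1
    mu <- mu1
    s <- s1
    if (done) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(location = mu, scale = s, tuning_k = tuning_k,
         iterations = iter, converged = converged, degenerate = s == 0),
    class = "huber_estimates")
}

#' @export
print.huber_estimates <- function(x, ...) {
  cat(sprintf(
    "Huber M-estimates (k = %.3f): location = %.4f, scale = %.4f (%d iterations%s)\n",
    x$tuning_k, x$location, x$scale, x$iterations,
    if (x$degenerate) ", degenerate" else if (!x$converged) ", NOT converged" else ""))
  invisible(x)
}

#' Alpha-outlier region limits under a fitted normal model
#'
#' Given robust location/scale estimates, the alpha-outlier region is the
#' complement of the central \eqn{1-\alpha} probability mass of
#' \eqn{N(\hat\mu, \hat\sigma^2)}: observations outside
#' \eqn{\hat\mu \pm z_{1-\alpha/2}\,\hat\sigma} are declared outliers.
#'
#' @param est A `"huber_estimates"` object (or any list with `location`
#'   and `scale`).
#' @param alpha Outlier level in (0, 1); default 0.05.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
alpha_outlier_limits <- function(est, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (!is.numeric(est$scale) || !is.numeric(est$location)) {
    stop("est must carry numeric location and scale")
  }
  if (est$scale <= 0) stop("degenerate scale: outlier region undefined")
  z <- stats::qnorm(1 - alpha / 2)
  c(lower = est$location - z * est$scale,
    upper = est$location + z * est$scale)
}

#' Bidirectional Youden-index cutoffs between cases and controls
#'
#' For the low direction, candidate cutoffs are the midpoints between
#' adjacent distinct values of the pooled sample that lie below the control
#' median; each candidate c is scored with the Youden index
#' \eqn{J(c) = sens(c) + spec(c) - 1} where sens is the fraction of cases
#' below c and spec the fraction of controls at or above c. The high
#' direction is defined symmetrically above the control median. Ties in J
#' are broken toward the cutoff farthest from the control median
#' (maximally conservative flagging). A direction with no candidate, or
#' whose best J is not positive, returns an infinite sentinel (no calls in
#' that direction).
#'
#' @param cases,controls Numeric vectors (>= 2 values each).
#' @return List with `lower`, `upper` (cutoffs; `-Inf`/`Inf` sentinels),
#'   and the achieved indices `j_lower`, `j_upper`.
#' @export
youden_cutoffs <- function(cases, controls) {
  stopifnot(length(cases) >= 2L, length(controls) >= 2L)
  med <- stats::median(controls)
  pooled <- sort(unique(c(cases, controls)))
  mids <- if (length(pooled) > 1L) {
    (pooled[-1L] + pooled[-length(pooled)]) / 2
  } else numeric(0)

  pick <- function(cand, j, farthest_low) {
    if (length(cand) == 0L) return(list(cut = NA_real_, j = NA_real_))
    jmax <- max(j)
    best <- cand[j >= jmax - 1e-12]
    cut <- if (farthest_low) min(best) else max(best)
    list(cut = cut, j = jmax)
  }

  low_cand <- mids[mids < med]
  j_low <- vapply(low_cand, function(c) {
    mean(cases < c) + mean(controls >= c) - 1
  }, numeric(1))
  low <- pick(low_cand, j_low, farthest_low = TRUE)

  high_cand <- mids[mids > med]
  j_high <- vapply(high_cand, function(c) {
    mean(cases > c) + mean(controls <= c) - 1
  }, numeric(1))
  high <- pick(high_cand, j_high, farthest_low = FALSE)

  lower <- if (is.na(low$cut) || low$j <= 0) -Inf else low$cut
  upper <- if (is.na(high$cut) || high$j <= 0) Inf else high$cut
  list(lower = lower, upper = upper,
       j_lower = if (is.na(low$j)) 0 else low$j,
       j_upper = if (is.na(high$j)) 0 else high$j)
}

#' Call ASE-positive samples in a case/control cohort
#'
#' Two complementary callers. `"youden"` derives bidirectional cutoffs
#' separating cases from controls via [youden_cutoffs()]; it presumes the
#' controls are representative of the balanced (non-ASE) case bulk --
#' when the two bulks differ in location or spread, the Youden maximum
#' tracks that bulk difference rather than the outliers, so the
#' Mann-Whitney/F screens ([screening_tests()]) should be consulted
#' alongside. `"alpha_outlier"`
#' fits Huber M location/scale to the case fractions and declares samples
#' in the alpha-outlier region of the fitted normal ([alpha_outlier_limits()])
#' positive. Either way a sample is flagged if its fraction lies strictly
#' outside `[lower, upper]` (a sample exactly on a cutoff is negative).
#'
#' @param cohort Data frame with columns `sample_id`, `group`
#'   (`"case"`/`"control"`) and `fraction` (gDNA-corrected cDNA
#'   reference-allele fraction in \[0, 1\]).
#' @param method `"youden"` or `"alpha_outlier"`.
#' @param alpha Outlier level for the alpha-outlier method; default 0.05.
#' @param huber_k Huber tuning constant; default 1.345.
#' @return Object of class `"ase_call_result"`: list with `method`,
#'   `lower_cutoff`, `upper_cutoff`, `flags` (named logical over all
#'   samples), `n_positive` (flagged cases), `n_positive_controls`,
#'   and for the alpha-outlier method `alpha` and `estimates`.
#' @export
call_ase <- function(cohort, method = c("youden", "alpha_outlier"),
                     alpha = 0.05, huber_k = 1.345) {
  method <- match.arg(method)
  cohort <- validate_cohort(cohort)
  cases <- cohort$fraction[cohort$group == "case"]
  controls <- cohort$fraction[cohort$group == "control"]
  if (length(cases) < 2L) stop("ase_calling: no cases (need >= 2)")
  estimates <- NULL
  if (method == "youden") {
    if (length(controls) < 2L) {
      stop("ase_calling: Youden cutoffs need >= 2 controls")
    }
    cuts <- youden_cutoffs(cases, controls)
    lower <- cuts$lower
    upper <- cuts$upper
  } else {
    estimates <- huber_m(cases, tuning_k = huber_k)
    lim <- alpha_outlier_limits(estimates, alpha)
    lower <- lim[["lower"]]
    upper <- lim[["upper"]]
  }
  flags <- cohort$fraction < lower | cohort$fraction > upper
  names(flags) <- cohort$sample_id
  structure(
    list(method = method, lower_cutoff = lower, upper_cutoff = upper,
         flags = flags,
         n_positive = sum(flags[cohort$group == "case"]),
         n_positive_controls = sum(flags[cohort$group == "control"]),
         alpha = if (method == "alpha_outlier") alpha else NA_real_,
         estimates = estimates),
    class = "ase_call_result")
}

#' @export
print.ase_call_result <- function(x, ...) {
  cat(sprintf(
    "ASE calls (%s): cutoffs [%.4f, %.4f]; %d positive case(s), %d positive control(s)\n",
    x$method, x$lower_cutoff, x$upper_cutoff,
    x$n_positive, x$n_positive_controls))
  if (!is.null(x$estimates)) {
    print(x$estimates)
  }
  invisible(x)
}

#' Screening tests for cohort-level differences in location and spread
#'
#' Cases and controls are compared with the two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test for a difference in location and with the two-sided
#' variance-ratio F-test for a difference in variability (the latter is
#' sensitive to outlier-driven variance inflation).
#'
#' @inheritParams call_ase
#' @return Object of class `"screening_tests"`: list with `mw_p`,
#'   `f_test_p` (NA with a warning if a group is constant), `median_case`,
#'   `median_control`.
#' @export
screening_tests <- function(cohort) {
  cohort <- validate_cohort(cohort)
  cases <- cohort$fraction[cohort$group == "case"]
  controls <- cohort$fraction[cohort$group == "control"]
  if (length(cases) < 2L || length(controls) < 2L) {
    stop("screening tests need >= 2 samples per group")
  }
  mw <- suppressWarnings(
    stats::wilcox.test(cases, controls, alternative = "two.sided"))
  f_p <- if (stats::var(cases) == 0 || stats::var(controls) == 0) {
    warning("constant group: F-test undefined, reporting NA")
    NA_real_
  } else {
    stats::var.test(cases, controls)$p.value
  }
  structure(
    list(mw_p = mw$p.value, f_test_p = f_p,
         median_case = stats::median(cases),
         median_control = stats::median(controls)),
    class = "screening_tests")
}

#' @export
print.screening_tests <- function(x, ...) {
  cat(sprintf(
    "Screening tests: Mann-Whitney p = %.4g (medians %.3f vs %.3f); F-test p = %.4g\n",
    x$mw_p, x$median_case, x$median_control, x$f_test_p))
  invisible(x)
}
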